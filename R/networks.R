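#' Canonical functional network labels
#'
#' The seven large-scale cortical networks used throughout the package:
#' visual (`vis`), sensorimotor (`smn`), cingulo-opercular (`cing`),
#' default-mode (`dmn`), frontoparietal (`fpn`), auditory (`aud`) and
#' dorsal-attention (`dan`).
#'
#' @return Character vector of the seven network identifiers.
#' @export
network_names <- function() {
  c("vis", "smn", "cing", "dmn", "fpn", "aud", "dan")
}

# Relative sizes used to carve a parcellation into the seven networks.
# At 360 regions these give the canonical counts (56 visual regions,
# matching the visual-network subset used for restricted connectivity).
.network_sizes_360 <- c(vis = 56, smn = 60, cing = 56, dmn = 80,
                        fpn = 50, aud = 20, dan = 38)

#' Assign regions to the seven functional networks
#'
#' Produces a region-to-network map for a parcellation of `n_regions`
#' contiguous regions. For 360 regions the canonical network sizes are
#' used (visual = 56); for other sizes the same proportions are applied
#' and rounded so that every network keeps at least one region and no
#' region is left unassigned.
#'
#' @param n_regions Number of cortical regions (default 360).
#' @return Named character vector of length `n_regions`; names are region
#'   ids (`r001`, ...), values are network ids.
#' @export
default_network_map <- function(n_regions = 360) {
  if (n_regions < 7)
    stop_("need at least 7 regions to populate 7 networks, got %d", n_regions)
  props <- .network_sizes_360 / sum(.network_sizes_360)
  sizes <- pmax(floor(props * n_regions), 1)
  # distribute the remainder by largest fractional part
  rem <- n_regions - sum(sizes)
  frac <- props * n_regions - floor(props * n_regions)
  ord <- order(frac, decreasing = TRUE)
  i <- 1
  while (rem > 0) {
    nm <- names(props)[ord[(i - 1) %% 7 + 1]]
    sizes[nm] <- sizes[nm] + 1L
    rem <- rem - 1L
    i <- i + 1
  }
  while (rem < 0) {
    nm <- names(sizes)[which.max(sizes)]
    sizes[nm] <- sizes[nm] - 1L
    rem <- rem + 1L
  }
  labels <- rep(names(sizes), times = sizes)
  names(labels) <- sprintf("r%03d", seq_len(n_regions))
  labels
}

# region ids belonging to one network
regions_of <- function(network_map, network) {
  ids <- names(network_map)[network_map == network]
  if (length(ids) == 0) stop_("network '%s' has no regions", network)
  ids
}
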