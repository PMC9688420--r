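#' Default cortical region plan for the 39-channel montage
#'
#' Assigns each channel to one of three cortical regions covered by the probe
#' set: `frontal` (channels 1-16), `central` (channels 17-33 and 39) and
#' `occipital` (channels 34-38). The assignment follows the montage's
#' frontal/central/posterior block structure, with channel 36 sitting in the
#' occipital block (it projects approximately to the left middle occipital
#' gyrus) and channel 39 belonging to the central block.
#'
#' @param n_channels number of channels the plan must cover.
#' @return named character vector, `names = channel index`.
#' @export
default_region_plan <- function(n_channels = 39L) {
  if (n_channels == 39L) {
    reg <- c(rep("frontal", 16), rep("central", 17), rep("occipital", 5), "central")
  } else {
    reg <- rep(c("frontal", "central", "occipital"), length.out = n_channels)
  }
  stats::setNames(reg, seq_len(n_channels))
}

#' Generate a probe layout
#'
#' Builds the source-detector montage description used throughout the
#' pipeline. The default call reproduces the study geometry: 19 sources and
#' 15 detectors forming 39 measurement channels with ~3 cm source-detector
#' separation, partitioned into frontal/central/occipital blocks.
#'
#' Channel-to-optode assignment is deterministic: channel `i` pairs source
#' `((i-1) mod n_sources) + 1` with detector `((i-1) mod n_detectors) + 1`,
#' which yields unique pairs whenever `n_channels <= lcm(n_sources,
#' n_detectors)`.
#'
#' @param n_sources,n_detectors,n_channels montage dimensions.
#' @param region_plan named character vector mapping every channel index to
#'   one of `"frontal"`, `"central"`, `"occipital"`.
#' @param separation_cm source-detector distance per channel (recycled).
#' @return object of class `probe_layout` with elements `sources`,
#'   `detectors`, `channels` (data.frame: channel, source, detector),
#'   `region` (named character), `separation_cm`.
#' @examples
#' lay <- generate_probe_layout()
#' table(lay$region)
#' @export
generate_probe_layout <- function(n_sources = 19L, n_detectors = 15L,
                                  n_channels = 39L,
                                  region_plan = default_region_plan(n_channels),
                                  separation_cm = 3) {
  stopifnot(n_sources >= 1, n_detectors >= 1, n_channels >= 1)
  src <- ((seq_len(n_channels) - 1L) %% n_sources) + 1L
  det <- ((seq_len(n_channels) - 1L) %% n_detectors) + 1L
  pairs <- paste(src, det, sep = "-")
  if (anyDuplicated(pairs))
    stop("invalid layout: duplicate source-detector pair(s): ",
         paste(unique(pairs[duplicated(pairs)]), collapse = ", "))
  plan_idx <- suppressWarnings(as.integer(names(region_plan)))
  if (anyNA(plan_idx) || !all(seq_len(n_channels) %in% plan_idx))
    stop("region_plan must cover every channel 1..", n_channels,
         "; missing: ",
         paste(setdiff(seq_len(n_channels), plan_idx), collapse = ", "))
  region <- unname(region_plan[match(seq_len(n_channels), plan_idx)])
  bad <- setdiff(unique(region), c("frontal", "central", "occipital"))
  if (length(bad)) stop("unknown region label(s): ", paste(bad, collapse = ", "))
  structure(list(
    sources = paste0("S", seq_len(n_sources)),
    detectors = paste0("D", seq_len(n_detectors)),
    channels = data.frame(channel = seq_len(n_channels),
                          source = paste0("S", src),
                          detector = paste0("D", det)),
    region = stats::setNames(region, seq_len(n_channels)),
    separation_cm = rep_len(separation_cm, n_channels)
  ), class = "probe_layout")
}

#' @export
print.probe_layout <- function(x, ...) {
  cat("Probe layout:", length(x$sources), "sources,", length(x$detectors),
      "detectors,", nrow(x$channels), "channels\n")
  print(table(region = x$region))
  invisible(x)
}

n_channels <- function(layout) nrow(layout$channels)
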