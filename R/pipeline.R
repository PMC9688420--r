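# End-to-end orchestration and file I/O: cohort export/import, per-subject
# network metric tables, and the simulate -> preprocess -> connectivity ->
# metrics -> compare -> predict pipeline with a reproducibility manifest.

#' Per-subject nodal (and optionally global) network metrics
#'
#' For each recording: correlation matrix, binarization at `sparsity`, and
#' nodal global/local efficiency; optionally the random-network-normalized
#' global metrics (expensive: `n_random` rewired references per subject).
#'
#' @param recordings list of `hemo_recording`s (or `connectivity_matrix`s).
#' @param sparsity network sparsity used for nodal metrics (study
#'   convention: 0.25).
#' @param global also compute Cp/Lp/Gamma/Lambda/Sigma/Eglob/Eloc.
#' @param n_random,seed random-reference settings for `global = TRUE`.
#' @return list with matrices `enod` and `eloc_nodal` (subject x node),
#'   and, when `global`, data.frame `globals` (one row per subject).
#' @export
cohort_metrics <- function(recordings, sparsity = 0.25, global = FALSE,
                           n_random = 100L, seed = 1L) {
  n <- length(recordings)
  enod <- eloc <- NULL
  globals <- vector("list", n)
  for (i in seq_len(n)) {
    cm <- if (inherits(recordings[[i]], "connectivity_matrix"))
      recordings[[i]] else correlation_matrix(recordings[[i]])
    net <- binarize_at_sparsity(cm, sparsity)
    en <- nodal_global_efficiency(net)
    el <- nodal_local_efficiency(net)
    if (is.null(enod)) {
      enod <- matrix(NA_real_, n, length(en))
      eloc <- matrix(NA_real_, n, length(el))
    }
    enod[i, ] <- en
    eloc[i, ] <- el
    if (global)
      globals[[i]] <- global_metrics(net, n_random = n_random,
                                     seed = substream_seed(seed, "rewire", i))
  }
  out <- list(enod = enod, eloc_nodal = eloc, sparsity = sparsity)
  if (global) out$globals <- do.call(rbind, globals)
  out
}

#' Write a synthetic cohort to disk
#'
#' Plain-text export: clinical table (`clinical.csv`), per-subject time
#' series (`ts_<subject>.tsv`: time column plus one column per channel,
#' header carrying channel indices, with a JSON sidecar holding the
#' sampling rate), and the probe layout (`layout.json`).
#'
#' @param cohort result of [generate_hemo_cohort()].
#' @param dir output directory (created if needed).
#' @param layout probe layout to serialize alongside.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, layout = generate_probe_layout()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$subjects, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  write_layout(layout, file.path(dir, "layout.json"))
  for (rec in cohort$recordings)
    write_timeseries(rec, file.path(dir, paste0("ts_", rec$subject_id, ".tsv")))
  invisible(dir)
}

#' @rdname write_cohort
#' @param rec a `hemo_recording`.
#' @param path output TSV path; the sidecar is `<path>.json`.
#' @export
write_timeseries <- function(rec, path) {
  n <- nrow(rec$hbo)
  df <- data.frame(time = (seq_len(n) - 1) / rec$fs, rec$hbo,
                   check.names = FALSE)
  colnames(df) <- c("time", colnames(rec$hbo) %||% seq_len(ncol(rec$hbo)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(subject_id = rec$subject_id, fs = rec$fs),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
write_layout <- function(layout, path) {
  jsonlite::write_json(list(sources = layout$sources,
                            detectors = layout$detectors,
                            channels = layout$channels,
                            region = as.list(layout$region),
                            separation_cm = layout$separation_cm),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a probe layout from JSON
#' @param path JSON path written by [write_layout()].
#' @return a `probe_layout`.
#' @export
read_layout <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(sources = j$sources, detectors = j$detectors,
                 channels = as.data.frame(j$channels),
                 region = unlist(j$region),
                 separation_cm = j$separation_cm),
            class = "probe_layout")
}

#' Read a hemodynamic time series
#'
#' Reads a TSV written by [write_timeseries()] (or equivalent): `time`
#' column plus one column per channel, channel indices in the header. The
#' sampling rate comes from the JSON sidecar or the `fs` argument; columns
#' are re-indexed against the layout, so reordered headers are handled.
#' Channels whose longest missing-value run exceeds 10% of the recording
#' are pruned with a warning.
#'
#' @param path TSV path.
#' @param layout probe layout the channel columns must match.
#' @param fs sampling rate; overrides/replaces the sidecar.
#' @return a `hemo_recording` (HbO only; `hbr` filled with `NA`).
#' @export
read_timeseries <- function(path, layout, fs = NULL) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (anyNA(suppressWarnings(as.numeric(unlist(df[1, ])))))
    stop("corrupt time-series file ", path, ": non-numeric values in line 2")
  side <- paste0(path, ".json")
  sid <- NA_character_
  if (is.null(fs)) {
    if (!file.exists(side))
      stop("sampling rate unknown: no fs argument and no sidecar ", side)
    j <- jsonlite::read_json(side, simplifyVector = TRUE)
    fs <- j$fs
    sid <- j$subject_id %||% NA_character_
  }
  if (is.null(fs)) stop("sampling rate missing")
  chcols <- setdiff(colnames(df), "time")
  nch <- n_channels(layout)
  if (length(chcols) != nch)
    stop(length(chcols), " channel columns but layout has ", nch, " channels")
  ord <- match(as.character(seq_len(nch)), chcols)
  if (anyNA(ord))
    stop("header channel indices do not match layout channels 1..", nch)
  hbo <- as.matrix(df[, chcols[ord], drop = FALSE])
  colnames(hbo) <- seq_len(nch)
  mask <- rep(TRUE, nch)
  for (ch in seq_len(nch)) {
    nas <- rle(is.na(hbo[, ch]))
    if (any(nas$values & nas$lengths > 0.1 * nrow(hbo))) {
      mask[ch] <- FALSE
      warning("channel ", ch, " pruned: missing-value run exceeds 10%")
    }
  }
  new_hemo_recording(sid, hbo, hbr = hbo * NA_real_, fs = fs,
                     channel_mask = mask,
                     provenance = list(list(step = "read", path = path)))
}

#' Pipeline run configuration
#'
#' One auditable object holding every stage's parameters: the cohort spec,
#' preprocessing config, sparsity range, random-network count, SVR config,
#' stage toggles, output directory and master seed. All stage seeds derive
#' from the master seed through named substreams.
#'
#' @param spec a [cohort_spec()].
#' @param preprocess_cfg a [preprocess_config()].
#' @param svr_cfg an [svr_config()].
#' @param sparsity single sparsity for group comparisons.
#' @param n_random random networks per subject for global metrics.
#' @param stages character subset of
#'   `c("simulate", "connectivity", "metrics", "compare", "predict")`.
#' @param out_dir output directory (`NULL` = keep everything in memory).
#' @param seed master seed; overrides `spec$seed`.
#' @return list of class `run_config`.
#' @export
run_config <- function(spec = cohort_spec(), preprocess_cfg = preprocess_config(),
                       svr_cfg = svr_config(),
                       sparsity = 0.25, n_random = 100L,
                       stages = c("simulate", "connectivity", "metrics",
                                  "compare", "predict"),
                       out_dir = NULL, seed = NULL) {
  known <- c("simulate", "connectivity", "metrics", "compare", "predict")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  structure(list(spec = spec, preprocess_cfg = preprocess_cfg,
                 svr_cfg = svr_cfg, sparsity = sparsity,
                 n_random = as.integer(n_random), stages = stages,
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the toggled stages in order: simulate a cohort, build
#' connectivity matrices, compute nodal metrics at the configured sparsity,
#' compare groups channel-wise (with BH-FDR), and predict HAMD from the
#' strongest-deficit channel's nodal local efficiency within the patient
#' group via nested-CV SVR. When `out_dir` is set, each stage's tables and
#' a manifest (config hash, package version, seed, stage list) are written
#' as CSV/JSON.
#'
#' @param cfg a [run_config()].
#' @return list with the stage outputs that were produced: `cohort`,
#'   `metrics`, `comparison`, `prediction`, `manifest`.
#' @export
run_pipeline <- function(cfg = run_config()) {
  stages <- cfg$stages
  need <- function(stage, dep, have)
    if (stage %in% stages && !dep %in% stages && is.null(have))
      stop("stage '", stage, "' requires stage '", dep, "'")
  need("connectivity", "simulate", NULL)
  need("metrics", "connectivity", NULL)
  need("compare", "metrics", NULL)
  need("predict", "metrics", NULL)
  out <- list()
  layout <- generate_probe_layout()
  if ("simulate" %in% stages)
    out$cohort <- generate_hemo_cohort(cfg$spec, layout)
  if ("connectivity" %in% stages)
    out$connectivity <- lapply(out$cohort$recordings, correlation_matrix)
  if ("metrics" %in% stages)
    out$metrics <- cohort_metrics(out$connectivity, sparsity = cfg$sparsity,
                                  seed = cfg$spec$seed)
  if ("compare" %in% stages) {
    g1 <- out$cohort$subjects$group == "depression"
    out$comparison <- channelwise_compare(out$metrics$eloc_nodal[g1, , drop = FALSE],
                                          out$metrics$eloc_nodal[!g1, , drop = FALSE])
  }
  if ("predict" %in% stages) {
    g1 <- out$cohort$subjects$group == "depression"
    ch <- if (!is.null(out$comparison) && any(out$comparison$significant))
      out$comparison$node[which.min(out$comparison$p_fdr)]
    else cfg$spec$effect_channel
    feats <- out$metrics$eloc_nodal[g1, ch, drop = FALSE]
    pc <- cfg$svr_cfg
    pc$seed <- substream_seed(cfg$spec$seed, "cv", 0L)
    out$prediction <- svr_nested_cv(feats, out$cohort$subjects$hamd[g1], pc,
                                    name = paste0("eloc_nodal_ch", ch))
  }
  out$manifest <- list(package_version = as.character(utils::packageVersion("fnirsnet")),
                       seed = cfg$spec$seed, stages = stages,
                       sparsity = cfg$sparsity,
                       timestamp = format(Sys.time(), tz = "UTC"))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(out$cohort)) write_cohort(out$cohort, cfg$out_dir, layout)
    if (!is.null(out$metrics)) {
      utils::write.csv(data.frame(subject = out$cohort$subjects$subject,
                                  out$metrics$eloc_nodal),
                       file.path(cfg$out_dir, "eloc_nodal.csv"),
                       row.names = FALSE)
      utils::write.csv(data.frame(subject = out$cohort$subjects$subject,
                                  out$metrics$enod),
                       file.path(cfg$out_dir, "enod.csv"), row.names = FALSE)
    }
    if (!is.null(out$comparison))
      utils::write.csv(out$comparison, file.path(cfg$out_dir, "comparison.csv"),
                       row.names = FALSE)
    if (!is.null(out$prediction))
      jsonlite::write_json(out$prediction[c("r", "p", "r2", "name")],
                           file.path(cfg$out_dir, "prediction.json"),
                           auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(out$manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  out
}
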