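#' A GC-MS measurement run
#'
#' A run couples a metabolite x measurement intensity matrix with the
#' instrument's measurement-sequence manifest. The manifest rows follow the
#' injection order and carry a role — `sample`, `pool` (repeated injection
#' of a mixture of all extracts, for drift tracking) or `blank` — plus the
#' linked sample id for sample measurements.
#'
#' @param intensities numeric matrix, metabolites x measurements (`NA` =
#'   not detected); column names must match `manifest$measurement_id`.
#' @param manifest data.frame with measurement_id, role, sample_id (NA for
#'   pools/blanks), in injection order.
#' @return object of class `metabolite_run`.
#' @export
metabolite_run <- function(intensities, manifest) {
  stopifnot(is.matrix(intensities),
            all(c("measurement_id", "role") %in% names(manifest)),
            identical(colnames(intensities), manifest$measurement_id))
  if (!all(manifest$role %in% c("sample", "pool", "blank")))
    stop("manifest roles must be sample/pool/blank", call. = FALSE)
  if (any(intensities < 0, na.rm = TRUE))
    stop("intensities must be non-negative", call. = FALSE)
  structure(list(intensities = intensities, manifest = manifest),
            class = "metabolite_run")
}

#' @export
print.metabolite_run <- function(x, ...) {
  cat("metabolite_run:", nrow(x$intensities), "metabolites,",
      sum(x$manifest$role == "sample"), "samples,",
      sum(x$manifest$role == "pool"), "pools,",
      sum(x$manifest$role == "blank"), "blanks\n")
  invisible(x)
}

# role-restricted column indices
run_cols <- function(run, role) which(run$manifest$role == role)

#' Remove contaminant metabolites using blank measurements
#'
#' A metabolite is a contaminant when its mean intensity in blanks exceeds
#' `threshold` (default 75%) of its mean intensity in samples. By default
#' missing values count as 0 in both means (conservative removal); with
#' `detected_only = TRUE` the means are over detected values only.
#'
#' @param run a [metabolite_run()].
#' @param threshold blank/sample mean ratio above which a metabolite is
#'   removed (default 0.75; strictly greater).
#' @param detected_only compute means over detected values only.
#' @return list with `run` (kept metabolites) and `removed` (ids).
#' @export
blank_filter <- function(run, threshold = 0.75, detected_only = FALSE) {
  bl <- run_cols(run, "blank"); sm <- run_cols(run, "sample")
  if (!length(bl)) {
    warning("no blank measurements: blank filter is a pass-through",
            call. = FALSE)
    return(list(run = run, removed = character(0)))
  }
  if (!length(sm)) stop("no sample measurements", call. = FALSE)
  X <- run$intensities
  mean_of <- function(cols) {
    M <- X[, cols, drop = FALSE]
    if (!detected_only) M[is.na(M)] <- 0
    rowMeans(M, na.rm = TRUE)
  }
  mb <- mean_of(bl); ms <- mean_of(sm)
  removed <- rownames(X)[!is.na(mb) & mb > threshold * ms]
  kept <- setdiff(rownames(X), removed)
  list(run = metabolite_run(X[kept, , drop = FALSE], run$manifest),
       removed = removed)
}

#' Keep metabolites by detection prevalence
#'
#' A metabolite is kept when it is detected (present and > 0) in every pool
#' measurement and in at least `min_sample_frac` of sample measurements
#' (default 25%; use 0.90 for correlation workflows).
#'
#' @param run a [metabolite_run()].
#' @param min_sample_frac minimum fraction of samples with detection.
#' @param require_all_pools require detection in every pool (default TRUE).
#' @return list with `run` (kept metabolites) and `removed` (ids).
#' @export
prevalence_filter <- function(run, min_sample_frac = 0.25,
                              require_all_pools = TRUE) {
  po <- run_cols(run, "pool"); sm <- run_cols(run, "sample")
  X <- run$intensities
  detected <- !is.na(X) & X > 0
  ok_pool <- if (require_all_pools && length(po))
    rowSums(detected[, po, drop = FALSE]) == length(po) else TRUE
  ok_sample <- rowMeans(detected[, sm, drop = FALSE]) >= min_sample_frac
  keep <- ok_pool & ok_sample
  list(run = metabolite_run(X[keep, , drop = FALSE], run$manifest),
       removed = rownames(X)[!keep])
}

#' Normalize instrument drift against pooled QC injections
#'
#' Every measurement's intensity of a metabolite is divided by the mean of
#' that metabolite's intensities in up to two nearest preceding and up to
#' two nearest following pool injections (at most four pools; for a pool
#' measurement, itself excluded). Pools in which the metabolite was not
#' detected are skipped when forming the window. Measurements with no
#' usable pool value anywhere are left unnormalized and flagged.
#'
#' @param run a [metabolite_run()].
#' @return list with `run` (normalized), `flagged` (metabolite ids left
#'   unnormalized for lack of pool values).
#' @export
drift_normalize <- function(run) {
  X <- run$intensities
  pos <- seq_len(ncol(X))
  pool_pos <- run_cols(run, "pool")
  if (!length(pool_pos)) stop("no pool measurements in sequence",
                              call. = FALSE)
  N <- X
  flagged <- character(0)
  for (m in seq_len(nrow(X))) {
    pv <- X[m, pool_pos]
    usable <- pool_pos[!is.na(pv) & pv > 0]
    if (!length(usable)) {
      flagged <- c(flagged, rownames(X)[m])
      next
    }
    for (j in pos) {
      pre <- utils::tail(usable[usable < j], 2)
      post <- utils::head(usable[usable > j], 2)
      w <- c(pre, post)
      if (!length(w)) {
        flagged <- unique(c(flagged, rownames(X)[m]))
        next
      }
      N[m, j] <- X[m, j] / mean(X[m, w])
    }
  }
  if (length(flagged))
    warning("metabolite(s) without usable pool values left unnormalized: ",
            paste(flagged, collapse = ", "), call. = FALSE)
  list(run = metabolite_run(N, run$manifest), flagged = flagged)
}

#' Intracellular vs extracellular metabolite ratios
#'
#' For metabolites detected in both fractions, the ratio of intracellular to
#' extracellular normalized intensity per time-point (sample measurements
#' matched by sample id). Zero or missing extracellular values give missing
#' ratios.
#'
#' @param intra,extra [metabolite_run()] objects after filtering and
#'   normalization; sample measurements of both runs must share sample ids.
#' @return list with `ratios` (matrix metabolite x sample id) and `shared`
#'   (metabolite ids present in both runs).
#' @export
intra_extra_ratio <- function(intra, extra) {
  shared <- intersect(rownames(intra$intensities),
                      rownames(extra$intensities))
  si <- run_cols(intra, "sample"); se <- run_cols(extra, "sample")
  ids_i <- intra$manifest$sample_id[si]
  ids_e <- extra$manifest$sample_id[se]
  common <- intersect(ids_i, ids_e)
  A <- intra$intensities[shared, si[match(common, ids_i)], drop = FALSE]
  B <- extra$intensities[shared, se[match(common, ids_e)], drop = FALSE]
  R <- A / B
  R[!is.finite(R)] <- NA_real_
  R[is.na(B) | B == 0] <- NA_real_
  colnames(R) <- common
  list(ratios = R, shared = shared)
}
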