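#' Classify a starting cell count into a c0 class
#'
#' A count belongs to target class `t` when
#' `t * (1 - tol) <= count <= t * (1 + tol)` (boundaries inclusive, no
#' pre-rounding); counts matching no class return `NA`. Targets whose
#' tolerance bands overlap are a configuration error.
#'
#' @param count Integer starting cell count(s) (>= 0); vectorized.
#' @param targets Positive target starting cell numbers (e.g. `c(10, 20, 30)`).
#' @param tol Relative tolerance (default 0.10).
#' @return Target class per count (`NA` when unclassified).
#' @export
classify_c0 <- function(count, targets = c(10, 20, 30), tol = 0.10) {
  if (any(targets <= 0)) stop("targets must be positive", call. = FALSE)
  targets <- sort(targets)
  lo <- targets * (1 - tol); hi <- targets * (1 + tol)
  if (length(targets) > 1 && any(hi[-length(hi)] >= lo[-1]))
    stop("configuration error: c0 classes overlap after tolerance expansion",
         call. = FALSE)
  if (any(count < 0)) stop("counts must be >= 0", call. = FALSE)
  vapply(count, function(cc) {
    hit <- which(lo <= cc & cc <= hi)
    if (length(hit) == 1L) targets[hit] else NA_real_
  }, numeric(1))
}

stage_flags <- function(stage) {
  switch(stage,
         d0 = c("agglomeration_d0", "excess_cells_d0"),
         d1 = "invasive_at_drug_add_d1",
         d3 = c("staining_failure_d3", "conjoined_d3", "planar_growth_d3",
                "collapsed_d3"),
         stop("unknown stage: ", stage, call. = FALSE))
}

parse_flags <- function(x) {
  f <- strsplit(x, ";", fixed = TRUE)
  lapply(f, function(v) v[nzchar(v)])
}

#' Apply stage-specific inclusion criteria
#'
#' Drops records carrying any QC flag relevant to the given stage (day 0:
#' uncountable or crowded seeding; day 1: already invasive at drug
#' addition; day 3: staining failure, conjoined neighbours, planar
#' outgrowth, collapse). Flags are data -- from the synthetic ground truth
#' or user annotation -- not image computations. Drop reasons are attached
#' as attribute `"dropped"`.
#'
#' @param records data.frame with at least `id` and `qc_flags`
#'   (semicolon-separated flag string; see [qc_flag_names()]).
#' @param stage One of `"d0"`, `"d1"`, `"d3"`.
#' @return Filtered records with a `"dropped"` attribute
#'   (data.frame `id`, `reason`).
#' @export
apply_inclusion_criteria <- function(records, stage = c("d0", "d1", "d3")) {
  stage <- match.arg(stage)
  flags <- parse_flags(records$qc_flags)
  unknown <- setdiff(unique(unlist(flags)), qc_flag_names())
  if (length(unknown))
    stop("unknown QC flag(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  rel <- stage_flags(stage)
  hit <- vapply(flags, function(f) any(f %in% rel), logical(1))
  dropped <- data.frame(
    id = records$id[hit],
    reason = vapply(flags[hit], function(f)
      paste(intersect(f, rel), collapse = ";"), ""),
    stringsAsFactors = FALSE)
  out <- records[!hit, , drop = FALSE]
  attr(out, "dropped") <- dropped
  out
}

#' Pool batches with matched c0-class distributions
#'
#' Subsamples every batch to the per-class minimum count across batches so
#' all batches carry identical c0-class compositions (the largest common
#' distribution), which is the precondition for pooling replicates across
#' batches. Subsampling is without replacement under the seed; a batch
#' missing a required class makes pooling infeasible.
#'
#' @param batches Named list (>= 2) of record data.frames, each with a
#'   `c0_class` column.
#' @param targets c0 classes that must be matched.
#' @param seed Integer for deterministic subsampling.
#' @return List with `pooled` (combined data.frame with a `batch` column)
#'   and `report` (per batch and class: counts before/after).
#' @export
pool_matched_c0 <- function(batches, targets = c(10, 20, 30), seed = 1) {
  if (length(batches) < 2L)
    stop("pooling requires >= 2 batches", call. = FALSE)
  if (is.null(names(batches)))
    names(batches) <- paste0("batch", seq_along(batches))
  counts <- vapply(batches, function(b)
    vapply(targets, function(t) sum(b$c0_class == t, na.rm = TRUE),
           integer(1)), integer(length(targets)))
  counts <- matrix(counts, nrow = length(targets),
                   dimnames = list(targets, names(batches)))
  min_per_class <- apply(counts, 1, min)
  empty <- targets[min_per_class == 0]
  if (length(empty))
    stop("infeasible pooling: class ", paste(empty, collapse = ", "),
         " empty in at least one batch", call. = FALSE)
  with_seed(seed, {
    kept <- lapply(names(batches), function(bn) {
      b <- batches[[bn]]
      sel <- unlist(lapply(seq_along(targets), function(ti) {
        idx <- which(b$c0_class == targets[ti])
        if (length(idx) == min_per_class[ti]) idx
        else sort(sample(idx, min_per_class[ti]))
      }))
      cbind(batch = bn, b[sel, , drop = FALSE])
    })
    pooled <- do.call(rbind, kept)
    rownames(pooled) <- NULL
    report <- data.frame(
      batch = rep(names(batches), each = length(targets)),
      c0_class = rep(targets, times = length(batches)),
      n_before = as.vector(counts),
      n_after = rep(min_per_class, times = length(batches)))
    list(pooled = pooled, report = report)
  })
}

#' Exponential growth rate from two counts
#'
#' Inverts the exponential growth model `c(t) = c0 * exp(r t)`:
#' `r = log(c_t / c0) / t` per hour.
#'
#' @param c0 Initial cell count (> 0).
#' @param c_t Count at time `t_hours` (> 0).
#' @param t_hours Elapsed time in hours (> 0).
#' @return List of class `growth_result`: `r`, `c0`, `c_t`, `t`.
#' @export
growth_rate <- function(c0, c_t, t_hours) {
  if (any(c0 <= 0) || any(c_t <= 0) || any(t_hours <= 0))
    stop("growth rate requires c0 > 0, c_t > 0, t > 0", call. = FALSE)
  structure(list(r = log(c_t / c0) / t_hours, c0 = c0, c_t = c_t,
                 t = t_hours), class = "growth_result")
}

#' Pooled-variance two-sample t-test
#'
#' Unpaired two-tailed Student's t-test assuming equal variances, with a
#' significance flag at alpha = 0.05. Degenerate data follow the
#' conventions: zero pooled variance with equal means gives t = 0, p = 1;
#' zero pooled variance with unequal means is an error.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @param alpha Significance level.
#' @return List: `t`, `df`, `p_value`, `significant`.
#' @export
compare_groups <- function(values_a, values_b, alpha = 0.05) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs n >= 2", call. = FALSE)
  if (any(!is.finite(values_a)) || any(!is.finite(values_b)))
    stop("values must be finite", call. = FALSE)
  na <- length(values_a); nb <- length(values_b)
  df <- na + nb - 2
  sp2 <- ((na - 1) * var(values_a) + (nb - 1) * var(values_b)) / df
  dm <- mean(values_a) - mean(values_b)
  if (sp2 == 0) {
    if (dm == 0) return(list(t = 0, df = df, p_value = 1,
                             significant = FALSE))
    stop("zero pooled variance with unequal means: t undefined",
         call. = FALSE)
  }
  tstat <- dm / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * pt(-abs(tstat), df)
  list(t = tstat, df = df, p_value = p, significant = p < alpha)
}
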