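# Longitudinal sample container: sphere-valued observations at sparse,
# irregular visit times, one set per subject.

#' Construct a longitudinal sample of sphere-valued observations
#'
#' @param ids Character vector of subject identifiers (one per subject).
#' @param times List of numeric visit-time vectors, one per subject, each
#'   sorted ascending.
#' @param obs List of matrices (one per subject, `m_i x 3`), each row a unit
#'   vector on the sphere (the square-root image of a composition).
#' @param group Optional character/factor vector of group labels per subject.
#' @return An object of class `longitudinal_sample`.
#' @export
longitudinal_sample <- function(ids, times, obs, group = NULL) {
  ids <- as.character(ids)
  n <- length(ids)
  stopifnot(length(times) == n, length(obs) == n)
  if (anyDuplicated(ids)) stop("duplicate subject ids")
  if (!is.null(group)) {
    group <- as.character(group)
    stopifnot(length(group) == n)
  }
  for (i in seq_len(n)) {
    ti <- as.numeric(times[[i]])
    Yi <- as.matrix(obs[[i]])
    if (length(ti) < 1) stop(sprintf("subject %s has no observations", ids[i]))
    if (is.unsorted(ti)) stop(sprintf("times not sorted for subject %s", ids[i]))
    if (nrow(Yi) != length(ti) || ncol(Yi) != 3)
      stop(sprintf("observation matrix shape mismatch for subject %s", ids[i]))
    nr <- sqrt(rowSums(Yi^2))
    if (any(abs(nr - 1) > 1e-6))
      stop(sprintf("non-unit observation for subject %s", ids[i]))
    times[[i]] <- ti
    obs[[i]] <- Yi / nr
  }
  structure(list(ids = ids, times = times, obs = obs, group = group),
            class = "longitudinal_sample")
}

#' @export
print.longitudinal_sample <- function(x, ...) {
  m <- lengths(x$times)
  cat(sprintf("Longitudinal sphere-valued sample: %d subjects, %d observations\n",
              length(x$ids), sum(m)))
  cat(sprintf("  visits per subject: %s (median %g)\n",
              paste(range(m), collapse = "-"), stats::median(m)))
  tr <- range(unlist(x$times))
  cat(sprintf("  time range: [%.3g, %.3g]\n", tr[1], tr[2]))
  if (!is.null(x$group)) {
    tb <- table(x$group)
    cat("  groups:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of subjects in a sample
#' @param sample A `longitudinal_sample`.
#' @return Integer.
#' @export
n_subjects <- function(sample) length(sample$ids)

# Flatten to pooled vectors/matrices (used by all estimators).
.pool_sample <- function(sample) {
  m <- lengths(sample$times)
  list(times = unlist(sample$times, use.names = FALSE),
       obs = do.call(rbind, sample$obs),
       subject = rep(seq_along(sample$ids), m),
       m = m)
}

#' Subset a longitudinal sample by subject
#'
#' @param sample A `longitudinal_sample`.
#' @param idx Integer or logical index over subjects, or character ids.
#'   Duplicated integer indices are allowed (bootstrap resampling); resampled
#'   subjects get fresh unique ids.
#' @return A `longitudinal_sample`.
#' @export
subset_subjects <- function(sample, idx) {
  if (is.character(idx)) idx <- match(idx, sample$ids)
  if (is.logical(idx)) idx <- which(idx)
  if (anyNA(idx)) stop("unknown subject id(s)")
  ids <- sample$ids[idx]
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "#")
  longitudinal_sample(ids, sample$times[idx], sample$obs[idx],
                      if (is.null(sample$group)) NULL else sample$group[idx])
}
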