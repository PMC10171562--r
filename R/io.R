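# Readers and writers: long-format delimited tables of compositional scans,
# fitted-model archives (JSON with full-precision numeric blocks), and JSON
# reports.

#' Read a long-format longitudinal table
#'
#' One row per scan with columns `subject_id`, `age`, `csf`, `gm`, `wm` and
#' an optional `group`. Comma- or tab-delimited (detected from the header
#' line). In `volumes` mode each row is divided by its row total (the
#' proportional-fraction formula `pWM = WM / (WM + GM + CSF)`); in
#' `proportions` mode rows must sum to 1 within `1e-6`. Ages are converted
#' from months to years when `unit = "months"` — the unit is always declared,
#' never guessed.
#'
#' @param path Path to the delimited text file.
#' @param mode `"proportions"` or `"volumes"`.
#' @param unit `"years"` or `"months"`.
#' @return A [longitudinal_sample()] (observations mapped to the sphere).
#' @export
read_longitudinal_table <- function(path, mode = c("proportions", "volumes"),
                                    unit = c("years", "months")) {
  mode <- match.arg(mode)
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("cannot read: ", path)
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = TRUE)
  req <- c("subject_id", "age", "csf", "gm", "wm")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  rows <- seq_len(nrow(df))
  bad <- function(cond, msg) {
    if (any(cond)) stop(sprintf("%s at row(s) %s", msg,
                                paste(utils::head(rows[cond], 10), collapse = ", ")))
  }
  age <- as.numeric(df$age)
  tis <- as.matrix(df[, c("csf", "gm", "wm")])
  storage.mode(tis) <- "double"
  bad(!is.finite(age) | age <= 0, "non-finite or non-positive age")
  bad(apply(!is.finite(tis), 1, any), "non-finite tissue value")
  bad(apply(tis < 0, 1, any), "negative tissue value")
  if (unit == "months") age <- age / 12
  rs <- rowSums(tis)
  if (mode == "volumes") {
    bad(rs <= 0, "zero row total in volume mode")
    tis <- tis / rs
  } else {
    bad(abs(rs - 1) > 1e-6, "tissue proportions do not sum to 1")
    tis <- tis / rs
  }
  key <- paste(df$subject_id, format(age, digits = 12))
  bad(duplicated(key), "duplicate (subject, age) row")

  ids <- unique(as.character(df$subject_id))
  times <- list(); obs <- list(); grp <- NULL
  has_group <- "group" %in% names(df)
  if (has_group) grp <- character(length(ids))
  for (i in seq_along(ids)) {
    sel <- which(as.character(df$subject_id) == ids[i])
    ord <- sel[order(age[sel])]
    times[[i]] <- age[ord]
    obs[[i]] <- t(apply(tis[ord, , drop = FALSE], 1, comp_to_sphere))
    if (has_group) {
      g <- unique(as.character(df$group[sel]))
      if (length(g) != 1)
        stop(sprintf("subject %s has inconsistent group labels", ids[i]))
      grp[i] <- g
    }
  }
  longitudinal_sample(ids, times, obs, group = grp)
}

#' Write a longitudinal sample as a long-format CSV
#'
#' Inverse of [read_longitudinal_table()] in `proportions` mode (ages in
#' years, full precision).
#'
#' @param sample A [longitudinal_sample()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_longitudinal_table <- function(sample, path) {
  rows <- list()
  for (i in seq_along(sample$ids)) {
    comp <- sample$obs[[i]]^2
    comp <- comp / rowSums(comp)
    rows[[i]] <- data.frame(
      subject_id = sample$ids[i],
      age = sprintf("%.17g", sample$times[[i]]),
      csf = sprintf("%.17g", comp[, 1]),
      gm = sprintf("%.17g", comp[, 2]),
      wm = sprintf("%.17g", comp[, 3]),
      group = if (is.null(sample$group)) "" else sample$group[i])
  }
  df <- do.call(rbind, rows)
  if (is.null(sample$group)) df$group <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save a fitted RFPCA model to a JSON archive
#'
#' Single-file archive: a header (options, grid, K, eigenvalues, noise
#' variance, FVE) plus dense numeric blocks (mean, eigenfunctions,
#' covariance, scores, pooled training observations) written with 17
#' significant digits so that [rfpca_load()] round-trips bit-exactly.
#'
#' @param fit An `rfpca_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
rfpca_save <- function(fit, path) {
  stopifnot(inherits(fit, "rfpca_fit"))
  obj <- list(
    format = "comptraj-rfpca-1",
    header = list(options = fit$options[!vapply(fit$options, is.null, logical(1))],
                  n_grid = length(fit$grid), K = fit$K,
                  lambda = fit$lambda, sigma2 = fit$sigma2, fve = fit$fve,
                  total_var = fit$total_var,
                  bandwidths = as.list(fit$bandwidths)),
    grid = fit$grid,
    mu = fit$mu,
    phi = list(dim = dim(fit$phi), data = as.vector(fit$phi)),
    Gamma = list(dim = dim(fit$Gamma), data = as.vector(fit$Gamma)),
    scores = fit$scores,
    ids = fit$ids,
    group = fit$group,
    pool = list(times = fit$pool$times, obs = fit$pool$obs,
                subject = fit$pool$subject))
  json <- jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Load a fitted RFPCA model from a JSON archive
#'
#' @param path Archive written by [rfpca_save()].
#' @return An `rfpca_fit`.
#' @export
rfpca_load <- function(path) {
  obj <- jsonlite::fromJSON(readLines(path, warn = FALSE))
  if (!identical(obj$format, "comptraj-rfpca-1"))
    stop("not a comptraj model archive: ", path)
  h <- obj$header
  opts <- do.call(rfpca_options, h$options)
  scores <- as.matrix(obj$scores)
  rownames(scores) <- obj$ids
  colnames(scores) <- NULL
  structure(list(
    grid = as.numeric(obj$grid),
    mu = as.matrix(obj$mu),
    Gamma = array(obj$Gamma$data, obj$Gamma$dim),
    lambda = as.numeric(h$lambda),
    phi = array(obj$phi$data, obj$phi$dim),
    sigma2 = as.numeric(h$sigma2),
    fve = as.numeric(h$fve),
    K = as.integer(h$K),
    total_var = as.numeric(h$total_var),
    bandwidths = unlist(h$bandwidths),
    options = opts,
    pool = list(times = as.numeric(obj$pool$times), obs = as.matrix(obj$pool$obs),
                subject = as.integer(obj$pool$subject)),
    ids = obj$ids,
    group = if (is.null(obj$group)) NULL else as.character(obj$group),
    scores = scores), class = "rfpca_fit")
}

#' Write a machine-readable JSON report
#'
#' @param x A list (e.g. an `energy_test` or benchmark summary, stripped of
#'   non-serializable members).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  x <- x[!vapply(x, function(e) is.function(e) || inherits(e, "rfpca_fit"), logical(1))]
  writeLines(jsonlite::toJSON(x, digits = I(17), auto_unbox = TRUE, null = "null",
                              force = TRUE), path)
  invisible(path)
}
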