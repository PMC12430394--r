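# The LR(ITA) protocol: single-descriptor ordinary-least-squares models
# of the post-Hartree-Fock electron correlation energy, with the
# R^2/RMSD summary statistics used by the packaged benchmark tables, and
# a separate evaluation verb for extrapolated predictions.

#' Fit a single-descriptor linear model
#'
#' Ordinary least squares with intercept of the correlation energy
#' (hartree) against one descriptor column.  The training-set quality
#' statistics follow the benchmark-table conventions: `r_squared = 1 -
#' SSR/SST` and `rmsd = sqrt(SSR/n)` reported in millihartree, with the
#' residual sum over all fitted points (no degree-of-freedom
#' correction).
#'
#' @param x descriptor values (a.u.; any fixed scaling is absorbed by
#'   the slope).
#' @param y correlation energies (hartree).
#' @param descriptor optional descriptor name carried in the model.
#' @return object of class `ita_lr` with `slope`, `intercept`,
#'   `n_points`, `r_squared` and `rmsd` (mH).
#' @export
fit_lr <- function(x, y, descriptor = NULL) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("insufficient data: need at least 3 points")
  if (max(x) - min(x) <= 1e-14 * max(abs(x), 1)) {
    stop("degenerate fit: descriptor values are constant")
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  res <- fit$residuals
  sst <- sum((y - mean(y))^2)
  structure(
    list(slope = unname(fit$coefficients[2]),
         intercept = unname(fit$coefficients[1]),
         n_points = length(x),
         r_squared = 1 - sum(res^2) / sst,
         rmsd = sqrt(mean(res^2)) * 1000,
         descriptor = descriptor),
    class = "ita_lr"
  )
}

#' @export
print.ita_lr <- function(x, ...) {
  cat(sprintf(
    "<ita_lr%s: slope %.8g, intercept %.8g, n = %d, R^2 = %.3f, RMSD = %.1f mH>\n",
    if (is.null(x$descriptor)) "" else paste0(" [", x$descriptor, "]"),
    x$slope, x$intercept, x$n_points, round(x$r_squared, 3), x$rmsd))
  invisible(x)
}

#' Predict correlation energies from a fitted model
#'
#' @param object an `ita_lr` model.
#' @param x descriptor value(s).
#' @param ... unused.
#' @return predicted correlation energies (hartree).
#' @export
predict.ita_lr <- function(object, x, ...) {
  object$slope * x + object$intercept
}

#' Evaluate predictions against reference energies
#'
#' Prediction-set statistics for extrapolation workflows: unlike the
#' training-set `r_squared`/`rmsd` stored on the model by [fit_lr()],
#' these measure deviations of model predictions from reference values
#' that were not used in the fit.
#'
#' @param model an `ita_lr` model.
#' @param x descriptor values of the evaluation set.
#' @param y reference correlation energies (hartree).
#' @return list with `rmsd` (mH), `max_abs_dev` (mH) and `r_squared`
#'   (squared Pearson correlation of predicted vs reference).
#' @export
evaluate_lr <- function(model, x, y) {
  pred <- predict(model, x)
  dev <- pred - y
  list(rmsd = sqrt(mean(dev^2)) * 1000,
       max_abs_dev = max(abs(dev)) * 1000,
       r_squared = stats::cor(pred, y)^2)
}

#' Read a packaged benchmark table
#'
#' Parses the CSV transcriptions under `inst/extdata/tables/` (or any
#' file in the same layout): `#` header lines carry provenance, the
#' column scales (`scale: if=1e3 ...`, meaning printed value x scale =
#' a.u.) and optionally a `flagged:` list of columns transcribed as
#' printed but known to contain typographical errors.
#'
#' @param name table name (e.g. `"table11_benzene"`) or a path to a CSV
#'   file.
#' @return data frame of class `ita_table` with attributes `scales`
#'   (named numeric), `flagged` (character) and `target` (name of the
#'   energy column, `"eps_mp2"`).
#' @export
read_ita_table <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("extdata", "tables", paste0(name, ".csv"),
                package = "itacorr")
  if (!nzchar(path) || !file.exists(path)) {
    stop("no packaged table or file named '", name, "'")
  }
  lines <- readLines(path)
  header <- grep("^#", lines, value = TRUE)
  tab <- utils::read.csv(text = paste(grep("^#", lines, invert = TRUE,
                                           value = TRUE),
                                      collapse = "\n"),
                         check.names = FALSE)
  scales <- stats::setNames(numeric(0), character(0))
  scale_ln <- grep("scale:", header, value = TRUE)
  if (length(scale_ln) > 0) {
    for (kv in strsplit(sub(".*scale:\\s*", "", scale_ln[1]), "\\s+")[[1]]) {
      p <- strsplit(kv, "=")[[1]]
      if (length(p) == 2) scales[p[1]] <- as.numeric(p[2])
    }
  }
  flag_ln <- grep("flagged:", header, value = TRUE)
  flagged <- if (length(flag_ln) > 0) {
    strsplit(trimws(sub(".*flagged:\\s*", "", flag_ln[1])), "\\s+")[[1]]
  } else character(0)
  flagged <- intersect(flagged, names(tab))
  if (!"eps_mp2" %in% names(tab)) stop("table lacks an eps_mp2 column")
  if (anyNA(tab$eps_mp2)) stop("missing target values in eps_mp2")
  structure(tab, scales = scales, flagged = flagged, target = "eps_mp2",
            class = c("ita_table", "data.frame"))
}

#' Names of the packaged benchmark tables
#' @return character vector usable with [read_ita_table()].
#' @export
list_ita_tables <- function() {
  sub("\\.csv$", "",
      list.files(system.file("extdata", "tables", package = "itacorr")))
}

#' Fit one model per descriptor column
#'
#' Runs [fit_lr()] of the target energy on every descriptor column of a
#' benchmark table and collects the per-column models plus a summary in
#' the benchmark layout (R^2 rounded to 3 decimals, RMSD in mH).
#'
#' @param table an `ita_table` (or data frame with an `eps_mp2` column;
#'   non-descriptor columns `n` and the target are skipped).
#' @return object of class `ita_lr_set`: list with `models` (named list
#'   of `ita_lr`), `summary` (data frame: descriptor, slope, intercept,
#'   r_squared, rmsd, flagged).
#' @export
fit_all <- function(table) {
  target <- attr(table, "target") %||% "eps_mp2"
  flagged <- attr(table, "flagged") %||% character(0)
  cols <- setdiff(names(table), c("n", "system", target))
  models <- lapply(cols, function(col)
    fit_lr(table[[col]], table[[target]], descriptor = col))
  names(models) <- cols
  structure(
    list(models = models,
         summary = data.frame(
           descriptor = cols,
           slope = vapply(models, `[[`, numeric(1), "slope"),
           intercept = vapply(models, `[[`, numeric(1), "intercept"),
           r_squared = round(vapply(models, `[[`, numeric(1), "r_squared"), 3),
           rmsd = vapply(models, `[[`, numeric(1), "rmsd"),
           flagged = cols %in% flagged,
           row.names = NULL)),
    class = "ita_lr_set"
  )
}

#' @export
print.ita_lr_set <- function(x, ...) {
  cat("LR(ITA) per-descriptor fits:\n")
  s <- x$summary
  s$rmsd <- round(s$rmsd, 1)
  print(s, row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
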