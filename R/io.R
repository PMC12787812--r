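#' Read and write isotherm CSV files
#'
#' The isotherm interchange format is a UTF-8 CSV with header
#' `ce_mg_per_L,qe_mg_per_kg`, one equilibrium record per row, `.` decimal
#' separator. Lines starting with `#` are metadata (e.g. generator seed) and
#' are skipped on read.
#'
#' @param path File path.
#' @return `read_isotherm_csv()` returns an [isotherm_data()].
#' @export
read_isotherm_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("ce_mg_per_L", "qe_mg_per_kg")
  if (!all(need %in% names(df)))
    stop("isotherm CSV must have columns ce_mg_per_L,qe_mg_per_kg",
         call. = FALSE)
  if (nrow(df) == 0L) stop("isotherm CSV is empty", call. = FALSE)
  isotherm_data(ce = df$ce_mg_per_L, qe = df$qe_mg_per_kg)
}

#' @rdname read_isotherm_csv
#' @param x An [isotherm_data()].
#' @param metadata Optional named list written as a `# key=value, ...`
#'   comment line.
#' @export
write_isotherm_csv <- function(x, path, metadata = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(metadata))
    writeLines(paste0("# ", paste(names(metadata), unlist(metadata),
                                  sep = "=", collapse = ", ")), con)
  writeLines("ce_mg_per_L,qe_mg_per_kg", con)
  writeLines(paste(format_num(x$ce), format_num(x$qe), sep = ","), con)
  invisible(path)
}

#' Read and write breakthrough-curve CSV files
#'
#' The breakthrough-curve interchange format is a CSV with header
#' `pv,c_rel`, monotone pore volumes, relative concentrations clipped at 0
#' on export. `#` metadata lines (seed, parameters, `hours_per_pv`) are
#' written above the header and skipped on read, except that a
#' `hours_per_pv=<value>` entry is restored into the [btc()] metadata.
#'
#' @param path File path.
#' @return `read_btc_csv()` returns a [btc()].
#' @export
read_btc_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^#", lines, value = TRUE)
  hpp <- NA_real_
  m <- regmatches(meta, regexpr("hours_per_pv=[0-9.eE+-]+", meta))
  m <- unlist(m)
  if (length(m)) hpp <- as.numeric(sub("hours_per_pv=", "", m[[1L]]))
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("pv", "c_rel") %in% names(df)))
    stop("btc CSV must have columns pv,c_rel", call. = FALSE)
  if (nrow(df) == 0L) stop("btc CSV is empty", call. = FALSE)
  btc(df$pv, df$c_rel, hours_per_pv = hpp)
}

#' @rdname read_btc_csv
#' @param x A [btc()].
#' @param metadata Optional named list of extra metadata entries.
#' @export
write_btc_csv <- function(x, path, metadata = NULL) {
  md <- list()
  if (!is.null(attr(x, "seed"))) md$seed <- attr(x, "seed")
  hpp <- attr(x, "hours_per_pv")
  if (!is.null(hpp) && is.finite(hpp)) md$hours_per_pv <- hpp
  md <- c(md, metadata)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(md))
    writeLines(paste0("# ", paste(names(md), unlist(md), sep = "=",
                                  collapse = ", ")), con)
  writeLines("pv,c_rel", con)
  writeLines(paste(format_num(x$pv), format_num(pmax(x$c_rel, 0)),
                   sep = ","), con)
  invisible(path)
}

format_num <- function(x) sprintf("%.15g", x)

na_str <- function(x, digits = 6) {
  ifelse(is.na(x), "NA", formatC(x, format = "g", digits = digits))
}

#' Write an isotherm fit report CSV
#'
#' Columns `treatment,kf,inv_n,r2_freundlich,kl,qmax,r2_langmuir`; cells of
#' non-converged Langmuir fits are written as the literal string `NA`.
#'
#' @param fits A named list, one element per treatment, each a list with
#'   elements `freundlich` (a `freundlich_fit`) and `langmuir` (a
#'   `langmuir_fit`, optional).
#' @param path Output path.
#' @export
write_isotherm_report <- function(fits, path) {
  rows <- vapply(names(fits), function(tr) {
    fr <- fits[[tr]]$freundlich
    lg <- fits[[tr]]$langmuir
    lg_vals <- if (is.null(lg) || !isTRUE(lg$converged))
      c("NA", "NA", "NA")
    else c(na_str(lg$kl), na_str(lg$qmax), na_str(lg$r2))
    paste(c(tr, na_str(fr$kf), na_str(fr$inv_n), na_str(fr$r2), lg_vals),
          collapse = ",")
  }, character(1))
  writeLines(c("treatment,kf,inv_n,r2_freundlich,kl,qmax,r2_langmuir", rows),
             path)
  invisible(path)
}

#' Write a breakthrough-curve fit report CSV
#'
#' Two-site reports use columns
#' `treatment,f,kd_L_per_kg,alpha_per_h,r2,rmse,converged,warnings`; tracer
#' reports use `treatment,v_cm_per_h,lambda_cm,D_cm2_per_h,r2,rmse,converged,warnings`.
#'
#' @param fit A `fit_result` from [fit_tracer_btc()] or [fit_two_site_btc()].
#' @param path Output path.
#' @param treatment Label for the first column.
#' @export
write_fit_report <- function(fit, path, treatment = "sample") {
  stopifnot(inherits(fit, "fit_result"))
  warn <- if (length(fit$warnings))
    paste(fit$warnings, collapse = "; ") else ""
  if (fit$model == "tracer CDE") {
    header <- "treatment,v_cm_per_h,lambda_cm,D_cm2_per_h,r2,rmse,converged,warnings"
    vals <- c(na_str(fit$params$v), na_str(fit$params$lambda),
              na_str(fit$params$D))
  } else {
    header <- "treatment,f,kd_L_per_kg,alpha_per_h,r2,rmse,converged,warnings"
    vals <- c(na_str(fit$params$f), na_str(fit$params$kd),
              na_str(fit$params$alpha))
  }
  row <- paste(c(treatment, vals, na_str(fit$r2), na_str(fit$rmse),
                 fit$converged, shQuote(warn, type = "cmd")), collapse = ",")
  writeLines(c(header, row), path)
  invisible(path)
}

#' Write a breakthrough-curve summary CSV
#'
#' Columns
#' `label,breakthrough_pv,peak_pv,peak_c_rel,mass_recovery_pv,elution_pv,threshold`.
#'
#' @param summary A `btc_summary` from [summarize_btc()], or a named list of
#'   them.
#' @param path Output path.
#' @export
write_btc_summary <- function(summary, path) {
  if (inherits(summary, "btc_summary")) summary <- list(sample = summary)
  rows <- vapply(names(summary), function(lbl) {
    s <- summary[[lbl]]
    paste(c(lbl, na_str(s$breakthrough_pv), na_str(s$peak_pv),
            na_str(s$peak_c_rel), na_str(s$mass_recovery_pv),
            na_str(s$elution_pv), na_str(s$threshold)), collapse = ",")
  }, character(1))
  writeLines(c("label,breakthrough_pv,peak_pv,peak_c_rel,mass_recovery_pv,elution_pv,threshold",
               rows), path)
  invisible(path)
}
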