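#' Save a result container to disk
#'
#' Structure-function, radial and fit results are written as a hierarchical
#' container (R serialization, `.rds`) holding the arrays together with the
#' lag list, wave-vector grid metadata, `dt`, `pixel_size`, the engine label
#' and the package version, so a result file is self-describing. Radial and
#' fit results can additionally be exported as plain CSV via
#' [export_radial_csv()] / [export_fit_csv()], or by giving `path` a `.csv`
#' extension here.
#'
#' @param x a `structure_function`, `radial_structure` or `isf_fit`.
#' @param path output path (`.rds`, or `.csv` for radial/fit results).
#' @return `path`, invisibly.
#' @seealso [load_results()]
#' @export
save_results <- function(x, path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    if (inherits(x, "radial_structure")) return(export_radial_csv(x, path))
    if (inherits(x, "isf_fit")) return(export_fit_csv(x, path))
    stop("CSV export is available for radial and fit results only",
         call. = FALSE)
  }
  payload <- unclass(x)
  container <- list(
    class = class(x)[1],
    payload = payload,
    meta = list(
      algorithm = if (!is.null(x$algorithm)) x$algorithm else NA_character_,
      software = "ddmsf",
      version = as.character(utils::packageVersion("ddmsf")),
      created = format(Sys.time(), tz = "UTC")
    )
  )
  ok <- tryCatch(saveRDS(container, path),
                 error = function(e)
                   stop("cannot write '", path, "': ", conditionMessage(e),
                        call. = FALSE))
  invisible(path)
}

#' Load a result container written by [save_results()]
#' @param path an `.rds` container path.
#' @return The stored object with its class restored; container metadata is
#'   attached as `attr(x, "meta")`.
#' @export
load_results <- function(path) {
  container <- readRDS(path)
  x <- structure(container$payload, class = container$class)
  attr(x, "meta") <- container$meta
  x
}

#' Export a radial structure function as CSV
#'
#' Long format (default) has one value row per ring and lag with columns
#' `q`, `lag`, `lag_time_s`, `d`. Wide format has one row per ring: `q`
#' followed by one column per lag time in seconds.
#'
#' @param rad a `radial_structure`.
#' @param path output `.csv` path.
#' @param format `"long"` (default) or `"wide"`.
#' @return `path`, invisibly.
#' @export
export_radial_csv <- function(rad, path, format = c("long", "wide")) {
  format <- match.arg(format)
  stopifnot(inherits(rad, "radial_structure"))
  if (format == "long") {
    df <- as.data.frame(tidy(rad))
  } else {
    df <- data.frame(q = rad$q_centers, rad$d_radial, check.names = FALSE)
    names(df) <- c("q", sprintf("t=%gs", rad$lags * rad$dt))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export per-ring ISF fit parameters (and D, if fitted) as CSV
#'
#' One row per ring: `q`, `A`, `B`, `tau`, `resid_norm`, `converged`; when
#' the diffusive fit has been run, constant columns `D`, `q_min`, `q_max`
#' record the pooled coefficient and its fitted range.
#'
#' @param fit an `isf_fit`.
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
export_fit_csv <- function(fit, path) {
  stopifnot(inherits(fit, "isf_fit"))
  df <- as.data.frame(fit$rings)
  if (!is.null(fit$diffusion)) {
    df$D <- fit$diffusion$D
    df$q_min <- fit$diffusion$q_min
    df$q_max <- fit$diffusion$q_max
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
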