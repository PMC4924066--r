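#' Construct an unbalanced panel of counts and covariates
#'
#' A `panel_data` object is a long-format table with one row per
#' (site, hour): a non-negative integer crash count, real-valued covariate
#' columns (indicators coded 0/1), and the names of the covariates entering
#' the count (negative binomial) state and the zero state.  Both designs
#' carry an implicit intercept.  The panel may be unbalanced: the number of
#' observations `t_i` can differ across sites.
#'
#' @param df data.frame with columns `site_id`, `time_id`, `count` and the
#'   covariates named in the designs.
#' @param count_design character vector of covariate names for the count
#'   state (`X_NBit`); the intercept is implicit.
#' @param zero_design character vector of covariate names for the zero
#'   state (`X_zit`); `character(0)` gives an intercept-only zero state.
#' @return An object of class `panel_data`: the validated data.frame with
#'   attributes `count_design` and `zero_design`.
#' @examples
#' df <- data.frame(site_id = c("a", "a", "b"), time_id = c(1, 2, 1),
#'                  count = c(0L, 1L, 0L), x = c(0.2, -0.1, 0.4))
#' pd <- panel_data(df, count_design = "x", zero_design = character(0))
#' nrow(pd)
#' @export
panel_data <- function(df, count_design = character(0),
                       zero_design = character(0)) {
  stopifnot(is.data.frame(df))
  required <- c("site_id", "time_id", "count")
  missing_cols <- setdiff(c(required, count_design, zero_design), names(df))
  if (length(missing_cols) > 0L) {
    stop("panel is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (any(!is.finite(df$count)) || any(df$count < 0) ||
      any(df$count != round(df$count))) {
    bad <- which(!is.finite(df$count) | df$count < 0 |
                   df$count != round(df$count))
    stop("count must be a non-negative integer; offending row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  df$count <- as.integer(df$count)
  key <- paste(df$site_id, df$time_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicated (site_id, time_id) pairs in panel", call. = FALSE)
  }
  for (v in union(count_design, zero_design)) {
    if (!is.numeric(df[[v]]) || any(!is.finite(df[[v]]))) {
      stop("covariate '", v, "' must be finite numeric", call. = FALSE)
    }
  }
  df$site_id <- as.character(df$site_id)
  structure(df,
            count_design = as.character(count_design),
            zero_design = as.character(zero_design),
            class = c("panel_data", "data.frame"))
}

#' @export
print.panel_data <- function(x, ...) {
  ti <- table(x$site_id)
  cat("Unbalanced count panel: ", nrow(x), " observations, ",
      length(ti), " sites (t_i ", min(ti), "-", max(ti), ")\n", sep = "")
  cat("count state: ~ 1",
      paste(c("", attr(x, "count_design")), collapse = " + "), "\n")
  cat("zero state : ~ 1",
      paste(c("", attr(x, "zero_design")), collapse = " + "), "\n")
  NextMethod()
}

# design matrices with explicit intercept, in spec order
panel_design <- function(data, which = c("count", "zero")) {
  which <- match.arg(which)
  vars <- attr(data, paste0(which, "_design"))
  X <- cbind("(Intercept)" = rep(1, nrow(data)))
  if (length(vars) > 0L) {
    X <- cbind(X, as.matrix(as.data.frame(data)[vars]))
    colnames(X) <- c("(Intercept)", vars)
  }
  X
}

#' Read a panel CSV file
#'
#' Expects columns `site_id,time_id,count,<covariate...>`.  Rows with
#' missing values in the count or any design covariate are dropped and
#' counted, mirroring the listwise deletion of segment-hours without
#' real-time traffic or environmental data in the assembly of the study
#' panel.
#'
#' @param path CSV file path.
#' @param count_design,zero_design covariate name lists, as [panel_data()].
#' @param quiet suppress the dropped-row message.
#' @return `panel_data` with attribute `n_dropped` (rows removed).
#' @export
read_panel_csv <- function(path, count_design = character(0),
                           zero_design = character(0), quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("site_id", "time_id", "count", count_design, zero_design)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("panel CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(bad <- !is.na(df$count) & df$count != round(df$count))) {
    stop("non-integer counts at row(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "), call. = FALSE)
  }
  need <- unique(c("site_id", "time_id", "count", count_design, zero_design))
  complete <- stats::complete.cases(df[need])
  n_dropped <- sum(!complete)
  if (!quiet && n_dropped > 0L) {
    message("read_panel_csv: dropped ", n_dropped,
            " row(s) with missing required fields")
  }
  pd <- panel_data(df[complete, , drop = FALSE],
                   count_design = count_design, zero_design = zero_design)
  attr(pd, "n_dropped") <- n_dropped
  pd
}

#' Write a panel to CSV
#'
#' @param data a `panel_data` (or plain data.frame).
#' @param path output path.
#' @export
write_panel_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summarize a panel in the layout of a study descriptive table
#'
#' Per-variable mean, standard deviation, minimum and maximum of the crash
#' count and every covariate column, plus panel dimensions (N, number of
#' sites, range of observations per site).
#'
#' @param data a `panel_data` or data.frame with `site_id`, `time_id`,
#'   `count` and numeric covariates.
#' @return object of class `panel_summary`: a data.frame of moments with
#'   attributes `n_obs`, `n_sites`, `t_i`.
#' @export
summarize_panel <- function(data) {
  if (nrow(data) == 0L) stop("empty panel", call. = FALSE)
  df <- as.data.frame(data)
  vars <- setdiff(names(df), c("site_id", "time_id"))
  vars <- vars[vapply(df[vars], is.numeric, logical(1))]
  tab <- data.frame(
    variable = vars,
    mean = vapply(df[vars], mean, numeric(1)),
    sd = vapply(df[vars], stats::sd, numeric(1)),
    min = vapply(df[vars], min, numeric(1)),
    max = vapply(df[vars], max, numeric(1)),
    row.names = NULL
  )
  ti <- as.integer(table(df$site_id))
  structure(tab, n_obs = nrow(df), n_sites = length(ti), t_i = ti,
            class = c("panel_summary", "data.frame"))
}

#' @export
print.panel_summary <- function(x, digits = 3, ...) {
  cat("Panel: N =", attr(x, "n_obs"), "observations,",
      attr(x, "n_sites"), "sites; t_i in [",
      min(attr(x, "t_i")), ",", max(attr(x, "t_i")), "]\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
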