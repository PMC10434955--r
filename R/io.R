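#' Read a one-column lifetime sample from a text file
#'
#' Accepts CSV/TSV/whitespace-separated text with a single numeric column,
#' with or without a header line (auto-detected). Non-numeric rows are
#' reported with their line numbers; nonpositive values are rejected.
#'
#' @param path readable file.
#' @return numeric vector of positive lifetimes with attribute
#'   \code{label} (the file name).
#' @export
read_lifetimes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty file: ", path, call. = FALSE)
  toks <- unlist(strsplit(trimws(lines[1]), "[,\t ;]+"))
  start <- if (suppressWarnings(anyNA(as.numeric(toks)))) 2L else 1L
  body <- lines[seq(start, length(lines))]
  vals <- suppressWarnings(as.numeric(
    unlist(lapply(body, function(l) strsplit(trimws(l), "[,\t ;]+")[[1]]))))
  per_line <- lapply(body, function(l) {
    suppressWarnings(as.numeric(strsplit(trimws(l), "[,\t ;]+")[[1]]))
  })
  bad <- which(vapply(per_line, anyNA, logical(1))) + start - 1L
  if (length(bad))
    stop("non-numeric value(s) at line(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  nonpos <- which(vapply(per_line, function(v) any(v <= 0), logical(1))) + start - 1L
  if (length(nonpos))
    stop("nonpositive lifetime(s) at line(s): ", paste(nonpos, collapse = ", "),
         call. = FALSE)
  structure(vals, label = basename(path))
}

#' The bundled 128 survival times (months)
#'
#' The classic remission/survival-time dataset of 128 bladder-cancer
#' patients (Lee and Wang, Statistical Methods for Survival Data
#' Analysis), shipped as a plain-text fixture. Summary: n = 128,
#' min = 0.08, max = 79.05, mean = 9.366, SD = 10.50833.
#'
#' @return numeric vector of length 128.
#' @examples
#' length(survival_times())
#' @export
survival_times <- function() {
  read_lifetimes(system.file("extdata", "survival_times.csv",
                             package = "ntsg", mustWork = TRUE))
}

#' Generate bundled or synthetic fixtures
#'
#' \code{"survival_times"} copies the verbatim 128-value dataset;
#' \code{"ntsw_sample"} writes seeded inverse-CDF draws from the amplified
#' sine-Weibull; \code{"incontrol_counts"} and \code{"shifted_counts"}
#' write seeded Binomial subgroup failure-count series for an in-control
#' process and a scale-shifted one (shift constant \code{c}).
#'
#' @param name one of \code{"survival_times"}, \code{"ntsw_sample"},
#'   \code{"incontrol_counts"}, \code{"shifted_counts"}.
#' @param dir output directory.
#' @param seed RNG seed for the stochastic fixtures.
#' @param params named list of parameters: for \code{ntsw_sample}
#'   \code{m}, \code{delta}, \code{alpha}, \code{lambda}; for the count
#'   fixtures \code{n_subgroups} plus a chart design (\code{n},
#'   \code{delta}, \code{lambda}, \code{k}, \code{tau}) and \code{c} for
#'   the shifted series.
#' @return path of the written file, invisibly.
#' @export
make_fixture <- function(name, dir = ".", seed = 1, params = list()) {
  choices <- c("survival_times", "ntsw_sample", "incontrol_counts",
               "shifted_counts")
  if (!name %in% choices)
    stop("unknown fixture '", name, "'; options: ",
         paste(choices, collapse = ", "), call. = FALSE)
  path <- file.path(dir, paste0(name, ".csv"))
  if (name == "survival_times") {
    file.copy(system.file("extdata", "survival_times.csv", package = "ntsg",
                          mustWork = TRUE), path, overwrite = TRUE)
    return(invisible(path))
  }
  set.seed(seed)
  if (name == "ntsw_sample") {
    p <- utils::modifyList(list(m = 100, delta = 2.5, alpha = 2.2,
                                lambda = 1.5), params)
    x <- rntsw(p$m, p$delta, p$alpha, p$lambda)
    utils::write.csv(data.frame(time = x), path, row.names = FALSE)
    return(invisible(path))
  }
  p <- utils::modifyList(list(n_subgroups = 50, n = 30, delta = 2.5,
                              lambda = 1.5, k = 2.981, tau = 0.948,
                              q = 0.5, c = 2), params)
  cc <- if (name == "incontrol_counts") 1 else p$c
  prob <- p_fail(p$tau, p$delta, p$lambda, p$q, c = cc)
  d <- stats::rbinom(p$n_subgroups, p$n, prob)
  utils::write.csv(data.frame(subgroup_id = seq_along(d), D = d), path,
                   row.names = FALSE)
  invisible(path)
}

#' Write a fit result as JSON and/or flat CSV
#'
#' @param fit an \code{"nts_fit"} object.
#' @param json,csv optional output paths.
#' @return the fit, invisibly.
#' @export
write_fit <- function(fit, json = NULL, csv = NULL) {
  stopifnot(inherits(fit, "nts_fit"))
  if (!is.null(json))
    jsonlite::write_json(list(model = fit$model,
                              estimates = as.list(fit$estimates),
                              loglik = fit$loglik,
                              converged = fit$converged,
                              n_starts = fit$n_starts,
                              n = length(fit$data)),
                         json, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv)) {
    df <- data.frame(model = fit$model, parameter = names(fit$estimates),
                     estimate = as.numeric(fit$estimates),
                     loglik = fit$loglik, converged = fit$converged)
    utils::write.csv(df, csv, row.names = FALSE)
  }
  invisible(fit)
}
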