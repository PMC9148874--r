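#' Challenge-style accuracy statistics
#'
#' RMSE, mean signed error (predicted minus experimental), Pearson
#' product-moment correlation and Kendall tau-b (identical to tau-a in the
#' absence of ties) between predicted and experimental binding free
#' energies. Invariant under a simultaneous permutation of the guests.
#'
#' @param predicted,experimental matched finite numeric vectors (kcal/mol),
#'   length >= 2 for the correlation statistics.
#' @return one-row data.frame with `n`, `rmse`, `me`, `pearson`, `kendall`.
#'   When either vector has zero variance, `pearson` is `NA` with a warning
#'   rather than an arbitrary number.
#' @examples
#' compute_stats(c(-9.4, -11.8, -12.2), c(-7.05, -9.94, -11.6))
#' @export
compute_stats <- function(predicted, experimental) {
  predicted <- as.numeric(predicted)
  experimental <- as.numeric(experimental)
  if (length(predicted) != length(experimental))
    stop("prediction and experiment vectors differ in length")
  if (!all(is.finite(predicted)) || !all(is.finite(experimental)))
    stop("values must be finite")
  if (length(predicted) < 2)
    stop("need at least 2 guests for correlation statistics")
  err <- predicted - experimental
  if (sd(predicted) == 0 || sd(experimental) == 0) {
    warning("zero variance: Pearson correlation undefined")
    r <- NA_real_
    tau <- suppressWarnings(cor(predicted, experimental,
                                method = "kendall"))
  } else {
    r <- cor(predicted, experimental)
    tau <- cor(predicted, experimental, method = "kendall")
  }
  data.frame(n = length(predicted), rmse = sqrt(mean(err^2)),
             me = mean(err), pearson = r, kendall = tau)
}

#' Percent RMSE reduction between two method variants
#'
#' `100 (1 - RMSE_after / RMSE_before)`; positive when the second method is
#' more accurate.
#'
#' @param stats_before,stats_after [compute_stats()] rows or bare RMSE
#'   numbers; `RMSE_before` must be positive.
#' @return percent reduction.
#' @export
rmse_reduction <- function(stats_before, stats_after) {
  get_rmse <- function(x) if (is.numeric(x) && length(x) == 1) x else
    x$rmse
  before <- get_rmse(stats_before); after <- get_rmse(stats_after)
  stopifnot(before > 0)
  100 * (1 - after / before)
}

#' Load a packaged prediction fixture
#'
#' `"table4"`: the per-guest binding free energies (kcal/mol, one decimal,
#' with uncertainties) of nine methods for the seven guests of a blind
#' host-guest challenge set (CB8 host), the experimental values, and the
#' published statistics columns for cross-checking.
#'
#' @param name fixture name; currently only `"table4"`.
#' @return list with `predictions` (data.frame: method, guest, value,
#'   uncertainty), `experiment` (data.frame: guest, value), `printed_stats`
#'   (data.frame: method, rmse, pearson, kendall, me) and `methods` (the
#'   method labels in table order).
#' @export
load_fixture <- function(name = "table4") {
  if (!identical(name, "table4")) stop("unknown fixture: ", name)
  path <- system.file("extdata", "table4.csv", package = "alchemfep",
                      mustWork = TRUE)
  spath <- system.file("extdata", "table4_stats.csv", package = "alchemfep",
                       mustWork = TRUE)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  stats <- read.csv(spath, stringsAsFactors = FALSE)
  experiment <- raw[raw$method == "Exp.", c("guest", "value")]
  predictions <- raw[raw$method != "Exp.", ]
  rownames(predictions) <- NULL
  rownames(experiment) <- NULL
  list(predictions = predictions, experiment = experiment,
       printed_stats = stats, methods = unique(predictions$method))
}

#' Recompute accuracy statistics for every method in a fixture
#'
#' @param fixture result of [load_fixture()], or a compatible list.
#' @param exclude_guests optional character vector of guest labels dropped
#'   from both predictions and experiment before computing statistics.
#' @return data.frame with one [compute_stats()] row per method.
#' @export
fixture_stats <- function(fixture, exclude_guests = character()) {
  ex <- fixture$experiment
  ex <- ex[!ex$guest %in% exclude_guests, ]
  out <- lapply(fixture$methods, function(m) {
    p <- fixture$predictions[fixture$predictions$method == m, ]
    p <- p[!p$guest %in% exclude_guests, ]
    p <- p[match(ex$guest, p$guest), ]
    if (any(is.na(p$value))) stop("guest sets differ for method ", m)
    cbind(data.frame(method = m), compute_stats(p$value, ex$value))
  })
  do.call(rbind, out)
}

#' Write / read a prediction table as CSV
#'
#' Plain long-format CSV (`method, guest, value, uncertainty`); a round trip
#' is lossless.
#'
#' @param predictions data.frame with columns method, guest, value and
#'   optionally uncertainty.
#' @param file path.
#' @export
write_prediction_table <- function(predictions, file) {
  stopifnot(all(c("method", "guest", "value") %in% names(predictions)))
  write.csv(predictions, file, row.names = FALSE, quote = TRUE)
  invisible(file)
}

#' @rdname write_prediction_table
#' @export
read_prediction_table <- function(file) {
  read.csv(file, stringsAsFactors = FALSE)
}
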