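#' Write a cohort to a long-format CSV file
#'
#' One row per subject and time point, columns `subject_id`, `time`
#' (1-based), `X`, `E`, `observed` (0/1). Rows with `observed = 0` are
#' retained with empty `X`/`E` fields, which keeps the monotone missingness
#' pattern explicit and checkable on read. Values are written with 17
#' significant digits so numeric round-trips are exact.
#'
#' @param cohort a `complete_cohort` or `attrition_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "complete_cohort"))
  n <- cohort$n; T <- cohort$T
  if (inherits(cohort, "attrition_cohort")) {
    obs <- cohort$observed
    v <- observed_values(cohort)
    X <- v$X; E <- v$E
  } else {
    obs <- matrix(TRUE, n, T)
    X <- cohort$X; E <- cohort$E
  }
  df <- data.frame(
    subject_id = rep(seq_len(n), times = T),
    time = rep(seq_len(T), each = n),
    X = ifelse(is.na(as.vector(X)), "", sprintf("%.17g", as.vector(X))),
    E = ifelse(is.na(as.vector(E)), "", as.character(as.vector(E))),
    observed = as.integer(as.vector(obs)),
    stringsAsFactors = FALSE)
  df <- df[order(df$subject_id, df$time), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format cohort CSV file
#'
#' Reads the schema written by [write_cohort_csv()] and reconstructs an
#' `attrition_cohort` from the observed data: unobserved cells are `NA`,
#' drop-out indicators are derived from the observability mask (a subject
#' with no observed event whose observation stops before the last time
#' point dropped out after their last observed time), and the endpoint is
#' known only where the observed data determine it (observed event, or
#' event-free and observed through the end). The monotone pattern is
#' validated; violations raise an error naming the offending subject.
#'
#' @param path input file path.
#' @return an `attrition_cohort`.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "time", "X", "E", "observed")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("cohort file lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  df$subject_id <- as.integer(df$subject_id)
  df$time <- as.integer(df$time)
  df$X <- as.numeric(df$X)
  df$E <- as.integer(df$E)
  df$observed <- as.integer(df$observed)
  ids <- sort(unique(df$subject_id))
  times <- sort(unique(df$time))
  T <- length(times)
  if (!identical(times, seq_len(T))) stop("time points must be 1..T")
  n <- length(ids)
  if (nrow(df) != n * T) stop("expected one row per subject and time point")
  df <- df[order(match(df$subject_id, ids), df$time), ]
  X <- matrix(df$X, n, T, byrow = TRUE)
  E <- matrix(df$E, n, T, byrow = TRUE)
  observed <- matrix(df$observed == 1L, n, T, byrow = TRUE)
  bad <- check_monotone(observed)
  if (length(bad)) {
    stop("non-monotone observability pattern for subject(s) ",
         paste(ids[utils::head(bad, 5)], collapse = ", "))
  }
  if (any(observed & (is.na(X) | is.na(E)))) {
    stop("observed rows must carry both X and E values")
  }
  X[!observed] <- NA_real_
  E[!observed] <- NA_integer_
  fet <- rep(NA_integer_, n)
  for (t in T:1) fet[!is.na(E[, t]) & E[, t] == 1L] <- t
  last_observed <- as.integer(rowSums(observed))
  D <- matrix(0L, n, T - 1L)
  for (t in seq_len(T - 1L)) {
    D[, t] <- as.integer(observed[, t] & !observed[, t + 1L] &
                           (is.na(fet) | fet > t))
  }
  endpoint <- ifelse(!is.na(fet), 1L,
                     ifelse(observed[, T], 0L, NA_integer_))
  structure(
    list(X = X, E = E,
         category = matrix(NA_integer_, n, T),
         first_event_time = fet, endpoint = endpoint,
         threshold = NA_real_, spec = NULL, n = n, T = T,
         D = D, observed = observed, last_observed = last_observed,
         subject_id = ids),
    class = c("attrition_cohort", "complete_cohort"))
}
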