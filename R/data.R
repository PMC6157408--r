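#' Round-robin family data
#'
#' The canonical data container is a wide data frame with one row per
#' four-member family: a `family_id` column, the twelve dyadic measurement
#' columns `x_MF`, `x_MT`, ..., `x_ST` (actor-major order, `NA` for missing
#' cells), optional role-specific outcome columns `y_M`, `y_F`, `y_T`,
#' `y_S`, and optional family-level predictor columns `z_1`, `z_2`, ....
#'
#' `srm_data()` validates such a data frame (or builds one from a bare
#' 12-column matrix of dyad values) and returns it with class `srm_data`.
#'
#' @param x A data frame containing `family_id` and the 12 `x_*` columns
#'   (plus optional `y_*`/`z_*` columns), or an n x 12 numeric matrix of
#'   dyad values ordered as [srm_dyads()].
#' @param outcomes Optional data frame / matrix of outcome columns
#'   (`y_M` ... `y_S`) when `x` is a bare matrix.
#' @param predictors Optional data frame / matrix of predictor columns
#'   (`z_1` ...) when `x` is a bare matrix.
#' @param family_id Optional vector of unique family identifiers.
#' @return A data frame of class `srm_data`.
#' @export
srm_data <- function(x, outcomes = NULL, predictors = NULL, family_id = NULL) {
  dyad_cols <- paste0("x_", srm_dyads())
  if (is.matrix(x) || (is.data.frame(x) && !any(dyad_cols %in% names(x)))) {
    x <- as.matrix(x)
    if (ncol(x) != 12L)
      stop("dyad value matrix must have 12 columns", call. = FALSE)
    colnames(x) <- dyad_cols
    df <- data.frame(x, check.names = FALSE)
    if (!is.null(outcomes)) df <- cbind(df, as.data.frame(outcomes))
    if (!is.null(predictors)) df <- cbind(df, as.data.frame(predictors))
    if (is.null(family_id)) family_id <- seq_len(nrow(df))
    df <- cbind(data.frame(family_id = family_id), df)
  } else {
    df <- as.data.frame(x)
    if (is.null(df$family_id)) {
      df$family_id <- if (is.null(family_id)) seq_len(nrow(df)) else family_id
    }
    df <- df[, c("family_id", setdiff(names(df), "family_id"))]
  }
  .validate_srm_data(df)
}

.validate_srm_data <- function(df) {
  dyad_cols <- paste0("x_", srm_dyads())
  missing_cols <- setdiff(dyad_cols, names(df))
  if (length(missing_cols))
    stop("missing mandatory dyad column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  unknown <- setdiff(grep("^x_", names(df), value = TRUE), dyad_cols)
  if (length(unknown))
    stop("unknown dyad column(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  if (nrow(df) < 1L) stop("need at least one family", call. = FALSE)
  if (anyDuplicated(df$family_id))
    stop("duplicate family_id: ",
         paste(unique(df$family_id[duplicated(df$family_id)]), collapse = ", "),
         call. = FALSE)
  for (cl in c(dyad_cols, grep("^[yz]_", names(df), value = TRUE)))
    if (!is.numeric(df[[cl]]))
      stop(sprintf("column %s must be numeric", cl), call. = FALSE)
  class(df) <- c("srm_data", "data.frame")
  df
}

# n x 12 matrix of dyad values (NA for missing), rownames = family_id
.dyad_matrix <- function(data) {
  stopifnot(inherits(data, "srm_data"))
  m <- as.matrix(data[, paste0("x_", srm_dyads())])
  colnames(m) <- srm_dyads()
  rownames(m) <- as.character(data$family_id)
  m
}

#' Fraction of families with at least one missing dyadic measurement
#'
#' @param data An [srm_data] object.
#' @return A proportion in `[0, 1]`.
#' @export
family_missing_rate <- function(data) {
  X <- .dyad_matrix(data)
  mean(rowSums(is.na(X)) > 0L)
}

#' Read and write round-robin CSV files
#'
#' The CSV dialect is comma-separated UTF-8 with a mandatory header row and
#' columns `family_id`, `x_MF`, ..., `x_ST`, then optional `y_*`/`z_*`
#' columns.  Missing values are written as empty fields; both empty fields
#' and the token `NA` are accepted on read.
#'
#' @param path Path to the CSV file.
#' @param quiet Suppress the row-count / missingness census message.
#' @return `read_round_robin_csv()` returns an [srm_data] object;
#'   `write_round_robin_csv()` returns `path` invisibly.
#' @export
read_round_robin_csv <- function(path, quiet = FALSE) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!"family_id" %in% names(raw))
    stop("missing mandatory column family_id", call. = FALSE)
  raw$family_id <- utils::type.convert(raw$family_id, as.is = TRUE)
  num_cols <- setdiff(names(raw), "family_id")
  for (cl in num_cols) {
    v <- trimws(raw[[cl]])
    v[v %in% c("", "NA")] <- NA_character_
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' in column %s, row %d",
                   v[bad[1L]], cl, bad[1L]), call. = FALSE)
    raw[[cl]] <- num
  }
  out <- .validate_srm_data(raw)
  if (!quiet) {
    X <- .dyad_matrix(out)
    message(sprintf(
      "read %d families; %d missing dyadic cells; %.1f%% of families have >=1 missing dyad",
      nrow(out), sum(is.na(X)), 100 * mean(rowSums(is.na(X)) > 0L)))
  }
  out
}

#' @rdname read_round_robin_csv
#' @param data An [srm_data] object.
#' @export
write_round_robin_csv <- function(data, path) {
  stopifnot(inherits(data, "srm_data"))
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Convert long-format round-robin data to the wide layout
#'
#' @param df A data frame with columns `family_id`, `actor`, `partner`
#'   (role labels among M, F, T, S) and `value`.
#' @return An [srm_data] object (one row per family).
#' @export
srm_data_from_long <- function(df) {
  need <- c("family_id", "actor", "partner", "value")
  if (!all(need %in% names(df)))
    stop("long format needs columns family_id, actor, partner, value",
         call. = FALSE)
  bad <- !(df$actor %in% srm_roles()) | !(df$partner %in% srm_roles()) |
    df$actor == df$partner
  if (any(bad)) stop("invalid actor/partner role pair in long data", call. = FALSE)
  ids <- unique(df$family_id)
  X <- matrix(NA_real_, length(ids), 12L,
              dimnames = list(NULL, srm_dyads()))
  rows <- match(df$family_id, ids)
  cols <- match(paste0(df$actor, df$partner), srm_dyads())
  if (anyDuplicated(cbind(rows, cols)))
    stop("duplicate (family, actor, partner) entries in long data", call. = FALSE)
  X[cbind(rows, cols)] <- df$value
  srm_data(X, family_id = ids)
}
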