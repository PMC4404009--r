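# Dataset readers/writers with validation.

#' Read a genus-level trait table
#'
#' Reads a CSV with required columns `D` and `W` (and usually `S`),
#' optional `genus`, `era`, and `diameter_cm`, validates every row
#' against the trait invariants (`0 <= D < 1`, `W >= 1`, `S > 0`,
#' `diameter_cm > 0`), and drops invalid rows with per-row diagnostics.
#'
#' @param path CSV file path.
#' @param require_S Is the `S` column required (3-D analyses)?
#' @return A `morpho_dataset` data frame; dropped-row diagnostics are
#'   attached as attribute `rejected` and reported via a warning.
#' @export
read_morpho_dataset <- function(path, require_S = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty dataset: ", path)
  required <- c("D", "W", if (require_S) "S")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required columns: ", paste(missing, collapse = ", "))
  }
  validate_morpho(df)
}

validate_morpho <- function(df) {
  msgs <- character(0)
  bad <- rep(FALSE, nrow(df))
  flag <- function(cond, msg) {
    cond[is.na(cond)] <- TRUE
    if (any(cond)) {
      msgs <<- c(msgs, sprintf("row %d: %s", which(cond), msg))
      bad <<- bad | cond
    }
  }
  flag(df$D < 0 | df$D >= 1, "D outside [0, 1)")
  flag(df$W < 1, "W below 1")
  if ("S" %in% names(df)) flag(df$S <= 0, "S not positive")
  if ("diameter_cm" %in% names(df)) {
    flag(!is.na(df$diameter_cm) & df$diameter_cm <= 0,
         "diameter_cm not positive")
  }
  if (!"genus" %in% names(df)) df$genus <- sprintf("genus_%04d", seq_len(nrow(df)))
  if (anyDuplicated(df$genus)) {
    flag(duplicated(df$genus), "duplicate genus id")
  }
  out <- df[!bad, , drop = FALSE]
  if (nrow(out) == 0L) stop("no valid rows left after validation")
  rownames(out) <- NULL
  if (length(msgs)) {
    warning(sprintf("dropped %d invalid row(s): %s", sum(bad),
                    paste(utils::head(msgs, 5L), collapse = "; ")),
            call. = FALSE)
  }
  attr(out, "rejected") <- msgs
  class(out) <- c("morpho_dataset", "data.frame")
  out
}

#' Write a genus table to CSV
#'
#' @param dataset A `morpho_dataset` (or plain data frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_morpho_dataset <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE)
  invisible(path)
}
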