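## Clinical-record (EHR) encoding: z-scoring of numeric fields and one-hot
## encoding of categorical fields. Statistics and vocabularies are learned on
## the training split only and frozen into an encoder state, so validation
## folds never leak into the standardization.

#' Describe one clinical field
#'
#' @param name Field name (a column of the clinical table).
#' @param kind `"numeric"` or `"categorical"`.
#' @return A schema entry (named list).
#' @export
ehr_field <- function(name, kind = c("numeric", "categorical")) {
  kind <- match.arg(kind)
  list(name = name, kind = kind)
}

#' Fit the clinical-vector encoder on a training split
#'
#' Computes, from the supplied records only, the per-field statistics needed
#' to encode clinical vectors: mean and standard deviation for numeric
#' fields (population convention, divisor `n`), and the sorted category
#' vocabulary for categorical fields. Categories unseen at encoding time map
#' to an all-zero one-hot group (with a warning).
#'
#' @param records Data frame of clinical records (training split).
#' @param schema List of [ehr_field()] entries, in output order.
#' @return An `ehr_encoder` object; its `length` is the encoded vector
#'   length `l`.
#' @export
fit_ehr_encoder <- function(records, schema) {
  if (length(schema) == 0L) stop("fit_ehr_encoder(): empty schema")
  if (nrow(records) == 0L) stop("fit_ehr_encoder(): no records")
  state <- lapply(schema, function(f) {
    if (!f$name %in% names(records)) {
      stop("fit_ehr_encoder(): field '", f$name, "' missing from records")
    }
    x <- records[[f$name]]
    if (f$kind == "numeric") {
      x <- as.double(x)
      if (any(!is.finite(x))) {
        stop("fit_ehr_encoder(): non-finite values in '", f$name, "'")
      }
      mu <- mean(x)
      sigma <- sqrt(mean((x - mu)^2))
      if (sigma <= 0) {
        stop("fit_ehr_encoder(): numeric field '", f$name,
             "' has zero variance")
      }
      list(name = f$name, kind = "numeric", mean = mu, sd = sigma, width = 1L)
    } else {
      vocab <- sort(unique(as.character(x)))
      if (length(vocab) == 0L) {
        stop("fit_ehr_encoder(): categorical field '", f$name, "' is empty")
      }
      list(name = f$name, kind = "categorical", vocab = vocab,
           width = length(vocab))
    }
  })
  out_names <- unlist(lapply(state, function(s) {
    if (s$kind == "numeric") s$name else paste0(s$name, "=", s$vocab)
  }))
  structure(list(fields = state, names = out_names,
                 length = length(out_names)),
            class = "ehr_encoder")
}

#' @export
print.ehr_encoder <- function(x, ...) {
  cat("<ehr_encoder> ", length(x$fields), " fields -> length ", x$length,
      "\n", sep = "")
  invisible(x)
}

#' Encode one clinical record as a fixed-length vector
#'
#' Numeric fields are z-scored with the stored training statistics;
#' categorical fields are one-hot encoded against the stored vocabulary
#' (unseen categories give an all-zero group plus a warning).
#'
#' @param record A one-row data frame or named list.
#' @param encoder An [fit_ehr_encoder()] state.
#' @return Named numeric vector of length `encoder$length`.
#' @export
encode_ehr <- function(record, encoder) {
  stopifnot(inherits(encoder, "ehr_encoder"))
  out <- numeric(0)
  for (s in encoder$fields) {
    if (is.null(record[[s$name]])) {
      stop("encode_ehr(): field '", s$name, "' missing from record")
    }
    x <- record[[s$name]]
    if (s$kind == "numeric") {
      out <- c(out, (as.double(x) - s$mean) / s$sd)
    } else {
      onehot <- as.double(s$vocab == as.character(x))
      if (sum(onehot) == 0) {
        warning("encode_ehr(): unseen category '", x, "' in field '",
                s$name, "'; encoding as all zeros")
      }
      out <- c(out, onehot)
    }
  }
  names(out) <- encoder$names
  out
}

#' Encode a clinical table as a matrix
#'
#' Row-wise [encode_ehr()]; rows are records, columns the encoded fields.
#'
#' @param records Data frame of clinical records.
#' @param encoder An [fit_ehr_encoder()] state.
#' @return Numeric matrix, `nrow(records)` x `encoder$length`.
#' @export
encode_ehr_table <- function(records, encoder) {
  t(vapply(seq_len(nrow(records)),
           function(i) encode_ehr(records[i, , drop = FALSE], encoder),
           numeric(encoder$length)))
}
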