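#' Truncate an ICD-10 code to its 3-character category
#'
#' Keeps the first three characters (letter + two digits) of a raw ICD-10
#' code and uppercases them, so e.g. sub-codes of the same disease category
#' collapse onto one vocabulary entry.
#'
#' @param raw_icd10 character vector of raw ICD-10 codes (e.g. "I25.1").
#' @return character vector of 3-character category codes (e.g. "I25").
#' @examples
#' truncate_code(c("I25.1", "E11", "c509"))
#' @export
truncate_code <- function(raw_icd10) {
  raw_icd10 <- as.character(raw_icd10)
  bad <- is.na(raw_icd10) | nchar(raw_icd10) < 3L |
    !grepl("^[A-Za-z]", raw_icd10)
  if (any(bad)) {
    stop_midrp("malformed ICD-10 code(s): %s",
               paste(utils::head(raw_icd10[bad], 5L), collapse = ", "))
  }
  toupper(substr(raw_icd10, 1L, 3L))
}

#' Read a diagnosis-event table
#'
#' Parses a TSV with columns \code{sample_id}, \code{icd10},
#' \code{admission_time} into a validated event table. Admission times may be
#' ISO dates (\code{YYYY-MM-DD}) or numeric days; they are re-expressed per
#' sample relative to that sample's earliest event and divided by
#' \code{time_unit}.
#'
#' @param path path to the events TSV.
#' @param time_unit length of one model time unit in days (default 30).
#' @return data.frame with columns sample_id, code, time.
#' @export
read_events <- function(path, time_unit = 30) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "")
  need <- c("sample_id", "icd10", "admission_time")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop_midrp("events file %s lacks column(s): %s", path,
               paste(miss, collapse = ", "))
  }
  raw_t <- df$admission_time
  if (all(grepl("^\\d{4}-\\d{2}-\\d{2}$", raw_t))) {
    days <- as.numeric(as.Date(raw_t))
  } else {
    days <- suppressWarnings(as.numeric(raw_t))
  }
  if (anyNA(days)) {
    bad <- which(is.na(days))[1L]
    stop_midrp("unparsable admission_time at data row %d: '%s'",
               bad, raw_t[bad])
  }
  events <- data.frame(sample_id = df$sample_id,
                       code = truncate_code(df$icd10),
                       time = days,
                       stringsAsFactors = FALSE)
  origin <- tapply(events$time, events$sample_id, min)
  events$time <- as.numeric(events$time - origin[events$sample_id]) /
    time_unit
  rownames(events) <- NULL
  events
}

#' Write a diagnosis-event table
#'
#' Inverse of \code{\link{read_events}} up to the time-unit rescale: writes
#' sample ids, codes and times in model units (column \code{admission_time},
#' numeric) as a TSV that \code{read_events(path, time_unit = 1)} reads back
#' exactly.
#'
#' @param events data.frame with sample_id, code, time.
#' @param path output path.
#' @export
write_events <- function(events, path) {
  out <- data.frame(sample_id = events$sample_id,
                    icd10 = events$code,
                    admission_time = format(events$time, digits = 17,
                                            scientific = FALSE, trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble per-sample event sequences
#'
#' Groups an event table by sample, sorts each group by admission time
#' (stable: ties keep file order) and drops samples with fewer than
#' \code{min_records} diagnoses.
#'
#' @param events data.frame from \code{\link{read_events}}.
#' @param min_records minimum number of diagnosis records per retained
#'   sample (default 2).
#' @return list of class \code{event_sequence_set}: \code{sequences} (named
#'   list; each element has \code{sample_id}, \code{codes}, \code{times}) and
#'   \code{dropped} (ids excluded by the record-count filter).
#' @export
assemble_sequences <- function(events, min_records = 2L) {
  if (nrow(events) == 0L) {
    return(structure(list(sequences = list(), dropped = character(0)),
                     class = "event_sequence_set"))
  }
  counts <- table(events$sample_id)
  keep_ids <- names(counts)[counts >= min_records]
  dropped <- setdiff(names(counts), keep_ids)
  idx <- split(seq_len(nrow(events)), events$sample_id)
  seqs <- lapply(keep_ids, function(id) {
    rows <- idx[[id]]
    ord <- order(events$time[rows])    # stable in R: ties keep input order
    structure(list(sample_id = id,
                   codes = events$code[rows][ord],
                   times = events$time[rows][ord]),
              class = "event_sequence")
  })
  names(seqs) <- keep_ids
  structure(list(sequences = seqs, dropped = dropped),
            class = "event_sequence_set")
}

#' Build an event-code vocabulary
#'
#' Maps each distinct 3-character code seen in the training corpus to an
#' integer id 1..K. Id 0 is reserved for padding and id K+1 for codes unseen
#' at training time.
#'
#' @param codes character vector of training-corpus codes (or an
#'   \code{event_sequence_set}).
#' @return list of class \code{event_vocabulary} with \code{code2id},
#'   \code{id2code}, \code{pad_id = 0}, \code{unk_id = K + 1}, \code{K}.
#' @export
build_vocabulary <- function(codes) {
  if (inherits(codes, "event_sequence_set")) {
    codes <- unlist(lapply(codes$sequences, `[[`, "codes"), use.names = FALSE)
  }
  uniq <- sort(unique(codes))
  code2id <- seq_along(uniq)
  names(code2id) <- uniq
  structure(list(code2id = code2id, id2code = uniq,
                 pad_id = 0L, unk_id = length(uniq) + 1L,
                 K = length(uniq)),
            class = "event_vocabulary")
}

#' Encode codes to integer ids
#' @param vocab an \code{event_vocabulary}.
#' @param codes character vector.
#' @return integer ids; unseen codes map to \code{vocab$unk_id}.
#' @export
encode_codes <- function(vocab, codes) {
  ids <- unname(vocab$code2id[codes])
  ids[is.na(ids)] <- vocab$unk_id
  as.integer(ids)
}

#' Decode integer ids back to codes
#' @param vocab an \code{event_vocabulary}.
#' @param ids integer ids (non-pad).
#' @return character codes; \code{unk_id} decodes to \code{"<UNK>"}.
#' @export
decode_ids <- function(vocab, ids) {
  out <- rep("<UNK>", length(ids))
  in_range <- ids >= 1L & ids <= vocab$K
  out[in_range] <- vocab$id2code[ids[in_range]]
  out
}

#' Serialize a vocabulary to JSON
#' @param vocab an \code{event_vocabulary}.
#' @param path output path.
#' @export
write_vocabulary <- function(vocab, path) {
  jsonlite::write_json(as.list(vocab$code2id), path, auto_unbox = TRUE)
  invisible(path)
}

#' Read a vocabulary from JSON
#' @param path JSON path written by \code{\link{write_vocabulary}}.
#' @return an \code{event_vocabulary}.
#' @export
read_vocabulary <- function(path) {
  m <- unlist(jsonlite::read_json(path))
  build_vocabulary(names(m)[order(unname(m))])
}

#' Clip and pad a sequence to a fixed model length
#'
#' Sequences longer than \code{max_len} keep the \code{max_len} most recent
#' events (disease risk depends most on recent history); shorter sequences
#' are right-padded with \code{pad_id}. A validity mask marks real positions;
#' padded positions are excluded from attention and loss downstream.
#'
#' @param seq an \code{event_sequence}.
#' @param vocab an \code{event_vocabulary}.
#' @param max_len model sequence length (>= 2).
#' @return list with \code{ids} (integer, length max_len), \code{times}
#'   (numeric; 0 at padded positions), \code{mask} (logical validity).
#' @export
clip_pad <- function(seq, vocab, max_len) {
  if (max_len < 2L) stop_midrp("max_len must be >= 2, got %d", max_len)
  ids <- encode_codes(vocab, seq$codes)
  times <- seq$times
  L <- length(ids)
  if (L > max_len) {
    keep <- (L - max_len + 1L):L
    ids <- ids[keep]
    times <- times[keep]
    L <- max_len
  }
  pad <- max_len - L
  list(ids = c(ids, rep(vocab$pad_id, pad)),
       times = c(times, rep(0, pad)),
       mask = c(rep(TRUE, L), rep(FALSE, pad)))
}

## Stack a list of event_sequences into batch matrices (ids, times, mask).
batch_sequences <- function(seqs, vocab, max_len) {
  B <- length(seqs)
  ids <- matrix(0L, B, max_len)
  times <- matrix(0, B, max_len)
  mask <- matrix(FALSE, B, max_len)
  for (b in seq_len(B)) {
    cp <- clip_pad(seqs[[b]], vocab, max_len)
    ids[b, ] <- cp$ids
    times[b, ] <- cp$times
    mask[b, ] <- cp$mask
  }
  list(ids = ids, times = times, mask = mask,
       sample_id = vapply(seqs, `[[`, "", "sample_id"))
}
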