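#' Validate a table of call records
#'
#' A call-record table has one row per call segment with columns
#' `segment_id`, `caller_id`, `call_type`, `sequence_id`, `timestamp`
#' (seconds since epoch), `audio_path` (may be empty when features are
#' supplied directly) and `quality_ok` (logical recording-quality flag).
#' Segments sharing a `sequence_id` belong to one vocalization and must
#' share caller and call type.
#'
#' @param records A data frame.
#' @return The validated data frame (invisibly unchanged).
#' @export
call_records <- function(records) {
  required <- c("segment_id", "caller_id", "call_type", "sequence_id",
                "timestamp", "quality_ok")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop_validation("missing record columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"audio_path" %in% names(records)) records$audio_path <- ""
  if (anyDuplicated(records$segment_id)) {
    stop_validation("segment_id values must be unique")
  }
  bad_type <- setdiff(unique(records$call_type), call_types())
  if (length(bad_type)) {
    stop_validation("unknown call type(s): ", paste(bad_type, collapse = ", "))
  }
  if (!is.logical(records$quality_ok)) {
    records$quality_ok <- as.logical(records$quality_ok)
  }
  if (!is.numeric(records$timestamp)) {
    stop_validation("timestamp must be numeric (seconds)")
  }
  per_seq <- split(records[c("caller_id", "call_type")], records$sequence_id)
  mixed <- vapply(per_seq, function(d) {
    length(unique(d$caller_id)) > 1L || length(unique(d$call_type)) > 1L
  }, logical(1))
  if (any(mixed)) {
    stop_validation("sequence(s) mixing callers or call types: ",
                    paste(names(per_seq)[mixed], collapse = ", "))
  }
  records
}

#' Apply the inclusion filters to call records
#'
#' Three filters are applied in order: (a) records whose `quality_ok` flag is
#' `FALSE` are dropped; (b) for call types built from repeated call segments,
#' only independent sequences are kept — a sequence is retained when it
#' starts at least `min_gap_s` after the previously retained sequence of the
#' same caller and call type (greedy, earliest first); (c) every
#' (caller, call type) pair with fewer than `min_calls` surviving segments is
#' removed entirely. The operation is idempotent.
#'
#' @param records A call-record table (see [call_records()]).
#' @param min_gap_s Minimum gap between sequence starts in seconds.
#' @param min_calls Minimum surviving segments per caller and call type.
#' @param repeated_types Call types subject to the sequence-independence rule.
#' @return The filtered records, in the original row order.
#' @export
filter_call_records <- function(records, min_gap_s = 3600, min_calls = 4,
                                repeated_types = repeated_call_types()) {
  if (nrow(records) == 0L) return(records)
  records <- call_records(records)
  keep <- records$quality_ok
  df <- records[keep, , drop = FALSE]
  if (nrow(df) == 0L) return(df)

  # sequence-independence rule for repeated-segment call types
  drop_seq <- character(0)
  rep_rows <- df$call_type %in% repeated_types
  if (any(rep_rows)) {
    sub <- df[rep_rows, , drop = FALSE]
    seq_start <- tapply(sub$timestamp, sub$sequence_id, min)
    seq_info <- unique(sub[c("sequence_id", "caller_id", "call_type")])
    seq_info$start <- as.numeric(seq_start[seq_info$sequence_id])
    for (grp in split(seq_info, list(seq_info$caller_id, seq_info$call_type),
                      drop = TRUE)) {
      grp <- grp[order(grp$start), , drop = FALSE]
      last_kept <- -Inf
      for (i in seq_len(nrow(grp))) {
        if (grp$start[i] - last_kept >= min_gap_s || !is.finite(last_kept)) {
          last_kept <- grp$start[i]
        } else {
          drop_seq <- c(drop_seq, grp$sequence_id[i])
        }
      }
    }
    df <- df[!(df$call_type %in% repeated_types &
                 df$sequence_id %in% drop_seq), , drop = FALSE]
  }
  if (nrow(df) == 0L) return(df)

  # minimum sample size per caller within call type
  cnt <- table(paste(df$caller_id, df$call_type, sep = "\r"))
  ok_pair <- names(cnt)[cnt >= min_calls]
  df[paste(df$caller_id, df$call_type, sep = "\r") %in% ok_pair, , drop = FALSE]
}
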