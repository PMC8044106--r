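#' Convert a count table into long-format strain frequencies
#'
#' Frequencies use assigned counts only as the denominator (ambiguous and
#' unassigned pairs were excluded from the study). Samples with zero assigned
#' pairs cannot be normalised; they are dropped with a warning.
#'
#' @param ct a \code{count_table} from [count_barcodes()].
#' @param sheet the \code{sample_sheet}; every counted sample must appear.
#' @return a \code{frequency_table}: long data.frame with columns sample_id,
#'   condition, incubation, mix, replicate, transfer, strain_id, frequency,
#'   assigned_total.
#' @export
to_frequencies <- function(ct, sheet) {
  sheet <- validate_sample_sheet(sheet)
  miss <- setdiff(rownames(ct$counts), sheet$sample_id)
  if (length(miss))
    stop("to_frequencies(): sample(s) in counts missing from sheet: ",
         paste(miss, collapse = ", "))
  totals <- rowSums(ct$counts)
  empty <- names(totals)[totals == 0]
  if (length(empty))
    warning("to_frequencies(): dropping sample(s) with no assigned pairs: ",
            paste(empty, collapse = ", "))
  keep <- rownames(ct$counts)[totals > 0]
  rows <- lapply(keep, function(sid) {
    meta <- sheet[sheet$sample_id == sid, ]
    data.frame(sample_id = sid,
               condition = meta$condition %||% NA,
               incubation = meta$incubation %||% NA,
               mix = meta$mix %||% NA,
               replicate = meta$replicate %||% NA,
               transfer = meta$transfer %||% NA,
               strain_id = colnames(ct$counts),
               frequency = ct$counts[sid, ] / totals[sid],
               assigned_total = totals[sid],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("frequency_table", "data.frame")
  out
}

#' Frequency table straight from a simulated trajectory
#'
#' Ground-truth convenience: turns one replicate's trajectory into the same
#' long format as [to_frequencies()], without the sequencing channel.
#'
#' @param traj a \code{competition_trajectory}.
#' @param condition,incubation,mix,replicate metadata stamped on every row.
#' @export
trajectory_frequencies <- function(traj, condition = "planktonic",
                                   incubation = "2d", mix = "A",
                                   replicate = 1L) {
  fr <- traj$frequencies
  out <- do.call(rbind, lapply(seq_len(nrow(fr)), function(i) {
    data.frame(sample_id = paste0(mix, replicate, "_", rownames(fr)[i]),
               condition = condition, incubation = incubation, mix = mix,
               replicate = replicate,
               transfer = i - 1L,
               strain_id = colnames(fr), frequency = fr[i, ],
               assigned_total = NA_integer_,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  class(out) <- c("frequency_table", "data.frame")
  out
}

#' Persistence: replicate populations in which a strain exceeds the input
#'
#' For each strain and condition regime, counts the replicate populations in
#' which the strain's frequency at the requested transfer is strictly greater
#' than the threshold — by default the equal-ratio input of 1/79 (the 1.27%
#' putative input).
#'
#' @param freqs a \code{frequency_table}.
#' @param transfer which transfer to evaluate (must be present).
#' @param threshold strict lower bound on frequency; default \code{1/79}.
#' @return data.frame with strain_id, condition, incubation, n_above,
#'   n_replicates.
#' @export
persistence <- function(freqs, transfer = 9L, threshold = 1 / 79) {
  sub <- freqs[freqs$transfer == transfer, ]
  if (nrow(sub) == 0)
    stop("persistence(): transfer ", transfer, " not present")
  agg <- aggregate(list(n_above = sub$frequency > threshold,
                        n_replicates = rep(1L, nrow(sub))),
                   by = list(strain_id = sub$strain_id,
                             condition = sub$condition,
                             incubation = sub$incubation),
                   FUN = sum)
  agg$n_above <- as.integer(agg$n_above)
  agg$n_replicates <- as.integer(agg$n_replicates)
  agg
}

#' Winners: strains exceeding a dominance threshold in each replicate
#'
#' A "winner" represents more than \code{threshold} of its population
#' (default 25%); at most \code{floor(1/threshold)} strains can win within one
#' sample.
#'
#' @param freqs a \code{frequency_table}.
#' @param transfer which transfer to evaluate.
#' @param threshold strict frequency bound; default 0.25.
#' @return data.frame with sample_id, condition, incubation, mix, replicate,
#'   strain_id, frequency — one row per winning strain (zero rows when none).
#' @export
winners <- function(freqs, transfer = 9L, threshold = 0.25) {
  sub <- freqs[freqs$transfer == transfer & freqs$frequency > threshold, ]
  rownames(sub) <- NULL
  sub[, c("sample_id", "condition", "incubation", "mix", "replicate",
          "strain_id", "frequency")]
}

#' @importFrom stats aggregate setNames
NULL
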