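#' Amplicon layout for synthetic barcode reads
#'
#' The sequenced template is
#' \code{forward_tag + left_flank + barcode + right_flank + revcomp(reverse_tag)}.
#' Read 1 is the first \code{read_length} bases of the template; read 2 is the
#' first \code{read_length} bases of its reverse complement, so it begins with
#' the reverse sample tag. Inline sample tags are 5 nt (forward) and 7 nt
#' (reverse), matching the 48-plex tagging scheme (4 forward x 12 reverse).
#'
#' @param forward_tag 5-nt tag on read 1.
#' @param reverse_tag 7-nt tag on read 2.
#' @param left_flank,right_flank fixed context around the 12-bp barcode
#'   (defaults emulate the amyE integration context).
#' @param read_length read length in bases; the barcode must fit entirely in
#'   read 1.
#' @export
amplicon_design <- function(forward_tag = "ACGTC",
                            reverse_tag = "TGCAGTC",
                            left_flank = "GATCCGTCAAGGAC",
                            right_flank = "CTGGATTCGAGCAA",
                            read_length = 50L,
                            barcode_length = 12L) {
  if (nchar(forward_tag) != 5) stop("amplicon_design(): forward_tag must be 5 nt")
  if (nchar(reverse_tag) != 7) stop("amplicon_design(): reverse_tag must be 7 nt")
  d <- list(forward_tag = forward_tag, reverse_tag = reverse_tag,
            left_flank = left_flank, right_flank = right_flank,
            read_length = as.integer(read_length),
            barcode_length = as.integer(barcode_length))
  if (5 + nchar(left_flank) + barcode_length > read_length)
    stop("amplicon_design(): barcode not fully contained in read 1 at this read_length")
  class(d) <- "amplicon_design"
  d
}

amplicon_template <- function(design, barcode) {
  paste0(design$forward_tag, design$left_flank, barcode, design$right_flank,
         revcomp(design$reverse_tag))
}

#' Render synthetic tagged paired-end reads for one sample
#'
#' Draws \code{depth} read pairs multinomially from a known strain
#' composition, builds each amplicon from the sample's tag pair and the
#' strain's barcode, applies iid per-base substitution errors, and returns the
#' pairs together with the ground-truth draw. Quality strings are constant
#' high-quality placeholders (the counting rules ignore quality).
#'
#' @param composition named numeric vector of strain frequencies (sums to 1);
#'   names must be strain_ids present in \code{library}.
#' @param design an [amplicon_design()].
#' @param library a \code{barcode_library} with strain assignments.
#' @param sample_id sample label used in read ids and the truth table.
#' @param depth number of read pairs.
#' @param error_rate per-base substitution probability.
#' @param seed optional seed (set before drawing).
#' @param tags optional length-2 list/vector (forward, reverse) overriding the
#'   design's sample tags, so one design can serve a whole multiplexed run.
#' @return a \code{read_set}: list with \code{id}, \code{seq1}, \code{seq2}
#'   character vectors and \code{truth} data.frame
#'   (sample_id, strain_id, true_count, true_frequency).
#' @export
render_reads <- function(composition, design, library, sample_id = "S1",
                         depth = 1000L, error_rate = 0, seed = NULL,
                         tags = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(tags)) {
    design$forward_tag <- tags[[1]]
    design$reverse_tag <- tags[[2]]
  }
  if (depth < 0) stop("render_reads(): depth must be >= 0")
  if (abs(sum(composition) - 1) > 1e-6)
    stop("render_reads(): composition frequencies must sum to 1")
  miss <- setdiff(names(composition), library$strain_id)
  if (length(miss))
    stop("render_reads(): strain(s) not in barcode library: ",
         paste(miss, collapse = ", "))
  bc <- library$barcode[match(names(composition), library$strain_id)]

  if (depth == 0) {
    draw <- setNames(rep(0L, length(composition)), names(composition))
  } else {
    draw <- as.vector(rmultinom(1, size = depth, prob = composition))
    names(draw) <- names(composition)
  }
  truth <- data.frame(sample_id = sample_id, strain_id = names(draw),
                      true_count = as.integer(draw),
                      true_frequency = if (depth > 0) draw / depth else 0,
                      stringsAsFactors = FALSE)

  templates <- amplicon_template(design, bc)
  L <- design$read_length
  seq1 <- substr(rep(templates, draw), 1L, L)
  seq2 <- substr(rep(revcomp(templates), draw), 1L, L)
  strain_of_read <- rep(names(draw), draw)

  if (error_rate > 0 && length(seq1)) {
    seq1 <- mutate_reads(seq1, error_rate)
    seq2 <- mutate_reads(seq2, error_rate)
  }
  ids <- if (length(seq1)) paste0(sample_id, ":", seq_along(seq1))
         else character(0)
  structure(list(id = ids, seq1 = seq1, seq2 = seq2,
                 strain = strain_of_read, truth = truth,
                 sample_id = sample_id),
            class = "read_set")
}

# iid substitution channel; only reads with >=1 error are touched
mutate_reads <- function(seqs, error_rate) {
  L <- nchar(seqs[1])
  n_err <- rbinom(length(seqs), size = L, prob = error_rate)
  hit <- which(n_err > 0)
  for (i in hit) {
    pos <- sample.int(L, n_err[i])
    ch <- strsplit(seqs[i], "")[[1]]
    for (p in pos) {
      ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1)
    }
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Write a read set (or several) as paired 4-line FASTQ files
#'
#' @param reads a \code{read_set} or list of them (concatenated in order).
#' @param r1_path,r2_path output FASTQ paths (".gz" suffix enables gzip).
#' @param truth_path optional path for the ground-truth TSV sidecar.
#' @return invisibly, the paths written.
#' @export
write_read_pairs <- function(reads, r1_path, r2_path, truth_path = NULL) {
  if (inherits(reads, "read_set")) reads <- list(reads)
  open_out <- function(p) if (grepl("\\.gz$", p)) gzfile(p, "w") else file(p, "w")
  con1 <- open_out(r1_path); on.exit(close(con1), add = TRUE)
  con2 <- open_out(r2_path); on.exit(close(con2), add = TRUE)
  for (rs in reads) {
    n <- length(rs$seq1)
    if (n == 0) next
    qual <- strrep("I", nchar(rs$seq1[1]))
    writeLines(paste0("@", rs$id, "/1\n", rs$seq1, "\n+\n", qual), con1)
    writeLines(paste0("@", rs$id, "/2\n", rs$seq2, "\n+\n", qual), con2)
  }
  if (!is.null(truth_path)) {
    truth <- do.call(rbind, lapply(reads, `[[`, "truth"))
    write.table(truth, truth_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(c(r1_path, r2_path))
}
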