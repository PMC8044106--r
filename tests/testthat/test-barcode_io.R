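sheet48 <- function() {
  ft <- generate_barcodes(4, 5, 2, seed = 21)$barcode
  rt <- generate_barcodes(12, 7, 2, seed = 22)$barcode
  make_sample_sheet(ft, rt)
}

test_that("demultiplex is exact by default and resolves 48 identities", {
  sheet <- sheet48()
  expect_equal(nrow(sheet), 48)

  # perfect prefixes recover every sample
  s1 <- paste0(sheet$forward_tag, "GATTACA")
  s2 <- paste0(sheet$reverse_tag, "GATTACA")
  expect_equal(demultiplex(s1, s2, sheet), sheet$sample_id)

  # one mismatched base in the 5-nt tag -> tag-unmatched
  bad <- s1[1]
  substr(bad, 1, 1) <- if (substr(bad, 1, 1) == "A") "C" else "A"
  expect_true(is.na(demultiplex(bad, s2[1], sheet)))

  # with tolerance 1 the same read is recovered
  expect_equal(demultiplex(bad, s2[1], sheet, tag_mismatches = 1),
               sheet$sample_id[1])
})

test_that("sample sheet invariants are enforced", {
  sheet <- sheet48()
  dup <- rbind(sheet, sheet[1, ])
  expect_error(validate_sample_sheet(dup), "unique")
  over <- sheet
  over$sample_id <- paste0("X", seq_len(nrow(over)))
  expect_error(validate_sample_sheet(rbind(sheet, over)), "at most 48|unique")
})

test_that("match_barcode implements the one-mate / multi-hit / exact rules", {
  lib <- tiny_library()
  b1 <- lib$barcode[1]
  b2 <- lib$barcode[2]
  pad <- function(b) paste0("TTTT", b, "TTTT")

  # intact on mate 1, garbled mate 2 -> assigned
  r <- match_barcode(pad(b1), "TTTTTTTTTTTTTTTT", lib)
  expect_equal(r$category, "assigned")
  expect_equal(r$strain_id, lib$strain_id[1])

  # two distinct barcodes across mates -> ambiguous
  expect_equal(match_barcode(pad(b1), pad(b2), lib)$category, "ambiguous")

  # two distinct barcodes on the same mate -> ambiguous
  expect_equal(match_barcode(paste0(b1, "TT", b2), "TTTT", lib)$category,
               "ambiguous")

  # same barcode on both mates -> assigned once
  r2 <- match_barcode(pad(b1), pad(b1), lib)
  expect_equal(r2$category, "assigned")

  # a single substitution breaks the 100%-identity rule
  mut <- b1
  substr(mut, 3, 3) <- if (substr(mut, 3, 3) == "A") "G" else "A"
  expect_equal(match_barcode(pad(mut), "TTTT", lib)$category, "unassigned")

  # reverse-complement occurrences: found by default, invisible without rc
  rcread <- pad(oracle_revcomp(b1))
  expect_equal(match_barcode(rcread, "TTTT", lib)$category, "assigned")
  expect_equal(match_barcode(rcread, "TTTT", lib, rc = FALSE)$category,
               "unassigned")
})

test_that("heterogeneous barcode lengths are rejected", {
  lib <- tiny_library()
  lib$barcode[1] <- "AAAA"
  expect_error(match_barcode("AAAA", "CCCC", lib), "heterogeneous")
})

test_that("oracle equivalence on constructed read pairs", {
  set.seed(31)
  lib <- tiny_library()
  cases <- replicate(300, {
    roll <- runif(1)
    mk <- function() paste(sample(c("A", "C", "G", "T"), 24, TRUE),
                           collapse = "")
    s1 <- mk(); s2 <- mk()
    if (roll < 0.3) {          # plant one barcode on a random mate/strand
      b <- sample(lib$barcode, 1)
      if (runif(1) < 0.5) b <- oracle_revcomp(b)
      if (runif(1) < 0.5) s1 <- paste0(substr(s1, 1, 8), b, substr(s1, 17, 24))
      else s2 <- paste0(substr(s2, 1, 8), b, substr(s2, 17, 24))
    } else if (roll < 0.5) {   # plant two distinct barcodes
      b <- sample(lib$barcode, 2)
      s1 <- paste0(b[1], substr(s1, 9, 24))
      s2 <- paste0(b[2], substr(s2, 9, 24))
    }
    c(s1, s2)
  })
  for (i in seq_len(ncol(cases))) {
    got <- match_barcode(cases[1, i], cases[2, i], lib)
    want <- oracle_assign(cases[1, i], cases[2, i], lib)
    expect_equal(got$category, want$category, info = paste("case", i))
    if (want$category == "assigned")
      expect_equal(got$strain_id, want$strain_id, info = paste("case", i))
  }
})

test_that("count_barcodes: lossless channel, conservation, empty input", {
  fx <- full_fixture()
  sheet <- sheet48()[1:2, ]
  comp <- setNames(rep(1 / 79, 79), fx$panel$strain_id)
  rs1 <- render_reads(comp, fx$design, fx$lib, sample_id = sheet$sample_id[1],
                      depth = 4000, error_rate = 0, seed = 5,
                      tags = c(sheet$forward_tag[1], sheet$reverse_tag[1]))
  rs2 <- render_reads(comp, fx$design, fx$lib, sample_id = sheet$sample_id[2],
                      depth = 3000, error_rate = 0, seed = 6,
                      tags = c(sheet$forward_tag[2], sheet$reverse_tag[2]))
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_read_pairs(list(rs1, rs2), f1, f2)

  ct <- count_barcodes(f1, f2, fx$lib, sheet)
  expect_equal(ct$total_pairs, 7000)
  expect_equal(unname(ct$counts[sheet$sample_id[1], rs1$truth$strain_id]),
               rs1$truth$true_count)
  expect_equal(unname(ct$counts[sheet$sample_id[2], rs2$truth$strain_id]),
               rs2$truth$true_count)
  # conservation
  expect_equal(sum(ct$summary$assigned) + sum(ct$summary$ambiguous) +
                 sum(ct$summary$unassigned) + ct$tag_unmatched,
               ct$total_pairs)

  # empty input
  e1 <- withr::local_tempfile(fileext = ".fastq")
  e2 <- withr::local_tempfile(fileext = ".fastq")
  file.create(e1); file.create(e2)
  ct0 <- count_barcodes(e1, e2, fx$lib, sheet)
  expect_equal(ct0$total_pairs, 0)
  expect_true(all(ct0$counts == 0))
})

test_that("desynchronized mates raise a format error naming the record", {
  fx <- full_fixture()
  sheet <- sheet48()[1, ]
  comp <- setNames(rep(1 / 79, 79), fx$panel$strain_id)
  rs <- render_reads(comp, fx$design, fx$lib, sample_id = sheet$sample_id,
                     depth = 10, error_rate = 0, seed = 1,
                     tags = c(sheet$forward_tag, sheet$reverse_tag))
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_read_pairs(rs, f1, f2)
  lines <- readLines(f2)
  lines[5] <- "@rogue_id/2"   # second record's header
  writeLines(lines, f2)
  expect_error(count_barcodes(f1, f2, fx$lib, sheet), "record 2")
})

test_that("noisy channel: assigned fraction follows the two-mate closed form", {
  fx <- full_fixture()
  sheet <- sheet48()[1, ]
  e <- 0.005
  depth <- 20000
  comp <- setNames(rep(1 / 79, 79), fx$panel$strain_id)
  rs <- render_reads(comp, fx$design, fx$lib, sample_id = sheet$sample_id,
                     depth = depth, error_rate = e, seed = 17,
                     tags = c(sheet$forward_tag, sheet$reverse_tag))
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_read_pairs(rs, f1, f2)
  ct <- count_barcodes(f1, f2, fx$lib, sheet)
  # P(barcode intact on one mate) = (1-e)^12; assigned needs >= 1 of 2 mates
  q <- (1 - e)^12
  expected <- 1 - (1 - q)^2
  tagged <- ct$total_pairs - ct$tag_unmatched
  frac <- sum(ct$summary$assigned) / tagged
  se <- sqrt(expected * (1 - expected) / tagged)
  expect_lt(abs(frac - expected), 4 * se)
})
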