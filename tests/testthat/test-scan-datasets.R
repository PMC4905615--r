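test_that("a mutation shared by two germlines yields two SH records", {
  ref <- toy_reference()
  # IGHV1-1*01 position 12 T -> A: IGHV3-9*01 carries A at 12;
  # IGHV1-1*02 carries T; IGHV4-2*01 carries T
  rr <- toy_rearr("P1", "IGHV1-1*01", "ACGTACGTACGA")
  scan <- sh_scan(rr, ref)
  expect_equal(nrow(scan$sh), 1)
  expect_equal(scan$sh$towg_allele, "IGHV3-9*01")
  expect_equal(nrow(scan$nonsh), 0)

  # position 1 A -> T: IGHV4-2*01 has T at 1, others A
  rr2 <- toy_rearr("P2", "IGHV1-1*01", "TCGTACGTACGT")
  scan2 <- sh_scan(rr2, ref)
  expect_equal(scan2$sh$towg_allele, "IGHV4-2*01")

  # position 5 A -> T from *01: shared with its own gene's *02 allele
  rr3 <- toy_rearr("P3", "IGHV1-1*01", "ACGTTCGTACGT")
  scan3 <- sh_scan(rr3, ref)
  expect_equal(scan3$sh$towg_allele, "IGHV1-1*02")
})

test_that("a base present in no germline at that column is non-SH", {
  ref <- toy_reference()
  # position 2 is C in every allele; C -> G occurs nowhere
  rr <- toy_rearr("P1", "IGHV1-1*01", "AGGTACGTACGT")
  scan <- sh_scan(rr, ref)
  expect_equal(nrow(scan$sh), 0)
  expect_equal(nrow(scan$nonsh), 1)
  expect_equal(scan$nonsh$nt_pos, 2L)
})

test_that("scan equals the brute-force triple loop on random instances", {
  for (seed in 1:25) {
    inst <- random_instance(seed)
    scan <- sh_scan(inst$rearr, inst$ref)
    oracle <- brute_force_scan(inst$rearr, inst$ref)
    expect_equal(canon(scan$sh[names(oracle$sh)]), canon(oracle$sh),
                 info = paste("seed", seed))
    expect_equal(canon(scan$nonsh[names(oracle$nonsh)]),
                 canon(oracle$nonsh), info = paste("seed", seed))
  }
})

test_that("every mutation is SH or non-SH, never both, and counts reconcile", {
  for (seed in 26:40) {
    inst <- random_instance(seed)
    scan <- sh_scan(inst$rearr, inst$ref)
    key <- function(d) paste(d$sequence_id, d$nt_pos)
    sh_keys <- unique(key(scan$sh))
    nonsh_keys <- key(scan$nonsh)
    expect_length(intersect(sh_keys, nonsh_keys), 0)
    expect_setequal(c(sh_keys, nonsh_keys), key(scan$mutations))
    expect_equal(length(sh_keys) + length(nonsh_keys),
                 nrow(scan$mutations))
    expect_equal(sum(scan$sequences$m_i), nrow(scan$mutations))
  }
})

test_that("conserved-only scan keeps exactly the mutations at conserved positions", {
  for (seed in 41:50) {
    inst <- random_instance(seed)
    whole <- sh_scan(inst$rearr, inst$ref)
    cons <- sh_scan(inst$rearr, inst$ref, conserved_only = TRUE)
    oracle <- brute_force_scan(inst$rearr, inst$ref,
                               conserved_only = TRUE)
    expect_equal(canon(cons$sh[names(oracle$sh)]), canon(oracle$sh))
    # subset relation plus exact difference
    key <- function(d) paste(d$sequence_id, d$nt_pos, d$towg_allele)
    expect_true(all(key(cons$sh) %in% key(whole$sh)))
    gene_per_seq <- setNames(gene_of_allele(inst$rearr$v_call),
                             inst$rearr$sequence_id)
    dropped <- dplyr::anti_join(whole$sh, cons$sh,
                                by = names(whole$sh))
    if (nrow(dropped) > 0) {
      at_conserved <- vapply(seq_len(nrow(dropped)), function(i) {
        g <- gene_per_seq[[dropped$sequence_id[i]]]
        dropped$nt_pos[i] %in% conserved_positions(inst$ref, g)
      }, logical(1))
      expect_false(any(at_conserved))
    }
  }
})

test_that("duplicate sequence identifiers are refused", {
  ref <- toy_reference()
  rr <- dplyr::bind_rows(
    toy_rearr("P1", "IGHV1-1*01", "ACGTACGTACGA"),
    toy_rearr("P1", "IGHV1-1*01", "ACGTACGTACGT"))
  expect_error(sh_scan(rr, ref), "duplicate")
})

test_that("pairwise identity counts only doubly-covered base positions", {
  expect_equal(pairwise_identity("ACGT", "ACGT"), 100)
  # 3 differences over 30 compared positions -> 90%
  a <- strrep("A", 30)
  b <- paste0(strrep("A", 27), "CCC")
  expect_equal(pairwise_identity(a, b), 90)
  # gaps and N drop out of numerator and denominator
  expect_equal(pairwise_identity("AC.T", "ACNT"), 100)
  expect_true(is.na(pairwise_identity("....", "ACGT")))
  expect_error(pairwise_identity("ACG", "ACGT"), "length")
})

test_that("GSHD rows aggregate SHPD rows per (sequence, towards germline)", {
  ref <- toy_reference()
  # two mutations both shared with IGHV3-9*01? craft: pos 12 T->A
  # (shared with 3-9) and pos 5 A->T (shared with 1-1*02)
  rr <- dplyr::bind_rows(
    toy_rearr("P1", "IGHV1-1*01", "ACGTTCGTACGA", subset = "#4"),
    toy_rearr("P2", "IGHV1-1*01", "ACGTACGTACGT", subset = "#4"))
  scan <- sh_scan(rr, ref)
  shpd <- build_shpd(scan, rr, ref)
  gshd <- build_gshd(scan, rr, ref)
  counts <- dplyr::count(shpd, .data$patient_id, .data$towg_allele)
  merged <- dplyr::inner_join(
    gshd, counts, by = c("patient_id", "towg_allele"))
  expect_equal(nrow(merged), nrow(gshd))
  expect_equal(merged$sh_count, merged$n)
  # sh_count column inside SHPD agrees with the group size
  expect_equal(
    dplyr::distinct(shpd, .data$patient_id, .data$towg_allele,
                    .data$sh_count)$sh_count,
    counts$n)
  # identity of TowG and sBm computed over compared positions
  row <- gshd[gshd$towg_allele == "IGHV3-9*01", ]
  expect_equal(row$identity_towg_sbm,
               pairwise_identity("ACGTACGTACGT", "ACGTACGTACGA"))
})

test_that("SHPD has the documented 34-column schema and consistent flags", {
  ref <- toy_reference()
  rr <- toy_rearr("P1", "IGHV1-1*01", "ACGTACGTACGA", subset = "#4")
  shpd <- build_shpd(sh_scan(rr, ref), rr, ref)
  expect_equal(ncol(shpd), 34)
  expect_equal(nrow(shpd), 1)
  expect_equal(shpd$towg_allele, "IGHV3-9*01")
  expect_equal(shpd$mutation, "t12a")
  expect_equal(shpd$towg_functionality, "F")
  expect_true(all(c("hydropathy_sbm", "hydropathy_sam",
                    "hydropathy_towg", "charge_towg") %in% names(shpd)))
})

test_that("nonSHPD annotates where the new chemical property is found", {
  ref <- toy_reference()
  rr <- toy_rearr("P1", "IGHV1-1*01", "AGGTACGTACGT", subset = "#4")
  scan <- sh_scan(rr, ref)
  nspd <- build_nonshpd(scan, rr, ref)
  expect_equal(nrow(nspd), 1)
  expect_false("towg_allele" %in% names(nspd))
  expect_true("new_property_functionality" %in% names(nspd))
  # codon 1 ACG(T) -> AGG(R): basic; germlines with a basic aa at
  # codon 1: IGHV1-1*01/*02/IGHV3-9*01 have T (hydroxyl), IGHV4-2*01
  # has S (hydroxyl) -> none basic
  expect_equal(nspd$new_property_functionality, "")
})

test_that("an empty scan produces empty tables that still carry headers", {
  ref <- toy_reference()
  rr <- toy_rearr("P1", "IGHV1-1*01", "ACGTACGTACGT")
  scan <- sh_scan(rr, ref)
  expect_equal(nrow(build_shpd(scan, rr, ref)), 0)
  expect_equal(ncol(build_shpd(scan, rr, ref)), 34)
  expect_equal(nrow(build_gshd(scan, rr, ref)), 0)
  expect_equal(ncol(build_gshd(scan, rr, ref)), 8)
  expect_equal(nrow(build_nonshpd(scan, rr, ref)), 0)
})
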