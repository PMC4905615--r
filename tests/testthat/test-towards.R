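# Exact rational oracle for the towards score, used to cross-check the
# floating-point implementation.
rational_score <- function(sh_num, sh_den, m, maxsh_num, maxsh_den,
                           selsc) {
  # score = (sh^2) / (m * maxsh * selsc) with sh = sh_num/sh_den and
  # maxsh = maxsh_num/maxsh_den, computed as one exact fraction
  num <- sh_num * sh_num * maxsh_den
  den <- sh_den * sh_den * m * maxsh_num * selsc
  num / den
}

test_that("raw lists count SH mutations per towards allele", {
  ref <- toy_reference()
  # P1: pos 5 A->T shared with IGHV1-1*02; pos 12 T->A shared with
  # IGHV3-9*01; pos 2 C->G non-SH
  rr <- dplyr::bind_rows(
    toy_rearr("P1", "IGHV1-1*01", "AGGTTCGTACGA", subset = "#4"),
    toy_rearr("P2", "IGHV1-1*01", "ACGTACGTACGT", subset = "#4"))
  raw <- build_raw_lists(sh_scan(rr, ref))
  expect_equal(nrow(raw), 2)
  el <- raw$elements[[1]]
  expect_equal(el$allele, c("IGHV1-1*02", "IGHV3-9*01"))
  expect_equal(el$sh_count, c(1L, 1L))
  expect_equal(raw$m_i, c(3L, 0L))
  expect_equal(raw$voting, c(TRUE, FALSE))
})

test_that("the towards score matches exact rational arithmetic", {
  # the worked case: SH=2, M=4, maxSH=5, selSc=1 -> 0.2
  expect_equal(towards_score(2, 4, 5, 1), 0.2)
  # 24 integer/half-integer tuples against the rational oracle
  cases <- expand.grid(sh = c(1, 2, 3), m = c(4, 7),
                       maxsh = c(3, 5), selsc = c(1, 2))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    expect_equal(towards_score(cs$sh, cs$m, cs$maxsh, cs$selsc),
                 rational_score(cs$sh, 1, cs$m, cs$maxsh, 1, cs$selsc),
                 tolerance = 1e-12)
  }
  # gene-level fractional SH and maxSH means (2 alleles)
  expect_equal(towards_score(3 / 2, 6, 7 / 2, 2),
               rational_score(3, 2, 6, 7, 2, 2), tolerance = 1e-12)
  expect_error(towards_score(1, 0, 5, 1), "m must be")
  expect_error(towards_score(1, 4, 0, 1), "maxsh")
})

test_that("scored lists implement the three-factor formula at gene level", {
  ref <- toy_reference()
  # P1 from IGHV1-1*01 with 4 mutations: pos 12 T->A (SH with
  # IGHV3-9*01), pos 2 C->G, pos 6 C->A, pos 7 G->T (non-SH)
  rr <- toy_rearr("P1", "IGHV1-1*01", "AGGTAATTACGA", subset = "#4")
  raw <- build_raw_lists(sh_scan(rr, ref))
  expect_equal(raw$m_i, 4L)
  scored <- score_lists(raw, ref, level = "gene")
  el <- scored$elements[[1]]
  # candidate IGHV3-9 (single allele): SH = 1, maxSH = dissimilarity
  # between IGHV1-1*01 and IGHV3-9*01 = 1, selSc = 1
  expect_equal(el$candidate, "IGHV3-9")
  expect_equal(el$score, towards_score(1, 4, 1, 1))
})

test_that("tied SH counts halve both scores through the selectivity factor", {
  # two single-allele candidate genes, both sharing the same mutation
  tbl <- tibble::tibble(
    allele = c("IGHV1-1*01", "IGHV3-1*01", "IGHV4-1*01"),
    gene = c("IGHV1-1", "IGHV3-1", "IGHV4-1"),
    subgroup = c(1L, 3L, 4L), functionality = "F", orphon = FALSE,
    partial_5prime = FALSE,
    nt_gapped = c("AAATTTCCCGGG", "CAATTTCCCGGG", "CAATTTCCCGGA"))
  ref <- ighv_reference(tbl)
  rr <- tibble::tibble(
    sequence_id = "P1", productive = TRUE, v_call = "IGHV1-1*01",
    v_identity = pairwise_identity("AAATTTCCCGGG", "CAATTTCCCGGG"),
    sequence_alignment = "CAATTTCCCGGG", mutations = list(NULL),
    subset = "#4")
  scored <- score_lists(build_raw_lists(sh_scan(rr, ref)), ref,
                        level = "gene")
  el <- scored$elements[[1]]
  expect_equal(el$candidate, c("IGHV3-1", "IGHV4-1"))
  # both genes share the single mutation (SH=1); maxSH: 3-1 differs
  # from sBm at 1 position, 4-1 at 2; selSc = 2 for both
  expect_equal(el$score[el$candidate == "IGHV3-1"],
               towards_score(1, 1, 1, 2))
  expect_equal(el$score[el$candidate == "IGHV4-1"],
               towards_score(1, 1, 2, 2))
  # removing the tie doubles the survivor's score
  solo <- score_lists(build_raw_lists(
    sh_scan(rr, ref[ref$gene != "IGHV4-1", ])),
    ref[ref$gene != "IGHV4-1", ], level = "gene")
  expect_equal(solo$elements[[1]]$score,
               2 * el$score[el$candidate == "IGHV3-1"])
})

test_that("gene-level SH and maxSH are allele means (zeros included)", {
  # candidate gene with 2 alleles, only one of which shares
  tbl <- tibble::tibble(
    allele = c("IGHV1-1*01", "IGHV3-1*01", "IGHV3-1*02"),
    gene = c("IGHV1-1", "IGHV3-1", "IGHV3-1"),
    subgroup = c(1L, 3L, 3L), functionality = "F", orphon = FALSE,
    partial_5prime = FALSE,
    nt_gapped = c("AAATTTCCCGGG", "CAATTTCCCGGG", "GAATTTCCCGGG"))
  ref <- ighv_reference(tbl)
  rr <- tibble::tibble(
    sequence_id = "P1", productive = TRUE, v_call = "IGHV1-1*01",
    v_identity = NA_real_, sequence_alignment = "CAATTTCCCGGG",
    mutations = list(NULL), subset = NA_character_)
  rr$v_identity <- pairwise_identity("AAATTTCCCGGG", rr$sequence_alignment)
  scored <- score_lists(build_raw_lists(sh_scan(rr, ref)), ref,
                        level = "gene")
  el <- scored$elements[[1]]
  # SH mean = (1 + 0)/2; maxSH mean = (1 + 1)/2 = 1; M = 1; selSc = 1
  expect_equal(el$score, towards_score(0.5, 1, 1, 1))
})

test_that("exclude_sbm_gene controls whether sibling alleles form a candidate", {
  ref <- toy_reference()
  # pos 5 A->T is shared only with the sibling allele IGHV1-1*02
  rr <- toy_rearr("P1", "IGHV1-1*01", "ACGTTCGTACGT")
  raw <- build_raw_lists(sh_scan(rr, ref))
  excl <- score_lists(raw, ref, level = "gene", exclude_sbm_gene = TRUE)
  expect_equal(nrow(excl$elements[[1]]), 0)
  incl <- score_lists(raw, ref, level = "gene", exclude_sbm_gene = FALSE)
  expect_equal(incl$elements[[1]]$candidate, "IGHV1-1")
})

test_that("homogenization zero-fills the union gene set in canonical order", {
  lists <- manual_scored_lists(list(
    list(candidates = "IGHV1-1", scores = 0.4),
    list(candidates = "IGHV3-9", scores = 0.2)))
  hom <- homogenize_lists(lists)
  expect_equal(hom$elements[[1]]$candidate, c("IGHV1-1", "IGHV3-9"))
  expect_equal(hom$elements[[1]]$score, c(0.4, 0))
  expect_equal(hom$elements[[2]]$score, c(0, 0.2))

  # identical gene sets are untouched
  same <- manual_scored_lists(list(
    list(candidates = c("A", "B"), scores = c(1, 2)),
    list(candidates = c("A", "B"), scores = c(3, 4))))
  hom2 <- homogenize_lists(same)
  expect_equal(hom2$elements[[2]]$score, c(3, 4))

  # union size equals the brute-force set union
  three <- manual_scored_lists(list(
    list(candidates = c("A", "B"), scores = c(1, 1)),
    list(candidates = c("B", "C"), scores = c(1, 1)),
    list(candidates = c("C", "D"), scores = c(1, 1))))
  hom3 <- homogenize_lists(three)
  expect_equal(nrow(hom3$elements[[1]]),
               length(union(union(c("A", "B"), c("B", "C")),
                            c("C", "D"))))
})

test_that("min-max normalization maps lists to [0,1] with fixed points", {
  lists <- manual_scored_lists(list(
    list(candidates = c("A", "B", "C"), scores = c(0, 0.1, 0.2))))
  norm <- normalize_lists(homogenize_lists(lists))
  expect_equal(norm$elements[[1]]$score, c(0, 0.5, 1))

  zero <- manual_scored_lists(list(
    list(candidates = c("A", "B"), scores = c(0, 0))))
  expect_equal(normalize_lists(homogenize_lists(zero))$elements[[1]]$score,
               c(0, 0))

  fixed <- manual_scored_lists(list(
    list(candidates = c("A", "B"), scores = c(1, 0))))
  expect_equal(normalize_lists(homogenize_lists(fixed))$elements[[1]]$score,
               c(1, 0))
})

test_that("aggregation is the arithmetic mean with deterministic ranking", {
  # one voter: consensus equals the voter's list
  one <- normalize_lists(homogenize_lists(manual_scored_lists(list(
    list(candidates = c("A", "B"), scores = c(0.8, 0.2))))))
  cr <- aggregate_lists(one)
  expect_equal(cr$candidate, c("A", "B"))
  expect_equal(cr$mean_score, c(1, 0))  # after min-max normalization

  # explicit mean across three voters
  three <- normalize_lists(homogenize_lists(manual_scored_lists(list(
    list(candidates = "A", scores = 1),
    list(candidates = "A", scores = 0),
    list(candidates = "A", scores = 0.5)))))
  # single-candidate lists degenerate: 1 -> 1, 0 -> 0, 0.5 -> 1
  cr3 <- aggregate_lists(three)
  expect_equal(cr3$mean_score, mean(c(1, 0, 1)))

  # symmetric 2x2: both genes at 50%
  sym <- normalize_lists(homogenize_lists(manual_scored_lists(list(
    list(candidates = c("A", "B"), scores = c(1, 0)),
    list(candidates = c("A", "B"), scores = c(0, 1))))))
  crs <- aggregate_lists(sym)
  expect_equal(crs$mean_score, c(0.5, 0.5))
  expect_equal(crs$pct_of_total, c(50, 50))
  expect_equal(crs$candidate, c("A", "B"))  # lexicographic tie-break
  expect_error(aggregate_lists(sym[0, ]), "zero voters")
})

test_that("aggregate equals the explicit voter-by-gene matrix mean", {
  for (seed in 1:20) {
    set.seed(seed)
    n_voters <- sample(1:10, 1)
    n_genes <- sample(1:10, 1)
    genes <- sprintf("G%02d", seq_len(n_genes))
    mat <- matrix(round(runif(n_voters * n_genes), 3),
                  nrow = n_voters)
    lists <- manual_scored_lists(purrr::map(seq_len(n_voters), ~ list(
      candidates = genes, scores = mat[.x, ])))
    attr(lists, "homogenized") <- TRUE
    attr(lists, "normalized") <- TRUE
    cr <- aggregate_lists(lists)
    oracle <- colMeans(mat)
    expect_equal(cr$mean_score[match(genes, cr$candidate)],
                 unname(oracle), tolerance = 1e-12)
  }
})

test_that("a voter with only non-SH mutations contributes zeros, not absence", {
  # two voters; voter 2 has mutations but no SH -> empty scored list
  lists <- manual_scored_lists(list(
    list(candidates = c("A", "B"), scores = c(0.5, 0.1), m = 4L),
    list(candidates = character(0), scores = numeric(0), m = 3L)))
  norm <- normalize_lists(homogenize_lists(lists))
  expect_equal(norm$elements[[2]]$score, c(0, 0))
  cr <- aggregate_lists(norm)
  # voter 1 normalizes to (1, 0); voter 2 contributes (0, 0)
  expect_equal(cr$mean_score[cr$candidate == "A"], 0.5)
  expect_equal(attr(cr, "n_voters"), 2L)
})

test_that("duplicating every voter leaves the consensus unchanged", {
  base <- manual_scored_lists(list(
    list(candidates = c("A", "B"), scores = c(0.7, 0.3)),
    list(candidates = c("B", "C"), scores = c(0.9, 0.1))))
  doubled <- manual_scored_lists(list(
    list(candidates = c("A", "B"), scores = c(0.7, 0.3)),
    list(candidates = c("B", "C"), scores = c(0.9, 0.1)),
    list(candidates = c("A", "B"), scores = c(0.7, 0.3)),
    list(candidates = c("B", "C"), scores = c(0.9, 0.1))))
  cr1 <- aggregate_lists(normalize_lists(homogenize_lists(base)))
  cr2 <- aggregate_lists(normalize_lists(homogenize_lists(doubled)))
  expect_equal(cr1$mean_score, cr2$mean_score)
  expect_equal(cr1$candidate, cr2$candidate)
})

test_that("scaling one voter's raw scores is erased by normalization", {
  v <- list(candidates = c("A", "B", "C"), scores = c(0, 0.2, 0.5))
  scaled <- list(candidates = v$candidates, scores = v$scores * 7)
  n1 <- normalize_lists(homogenize_lists(manual_scored_lists(list(v))))
  n2 <- normalize_lists(homogenize_lists(manual_scored_lists(list(scaled))))
  expect_equal(n1$elements[[1]], n2$elements[[1]])
})

test_that("clan summary averages per clan and rescales to 100", {
  ref <- toy_reference()
  mk_consensus <- function(genes, means) {
    structure(tibble::tibble(candidate = genes, mean_score = means,
                             pct_of_total = NA_real_),
              n_voters = 1L, level = "gene", group = "t",
              class = c("towards_consensus", class(tibble::tibble())))
  }
  # all movement into clan I
  cs <- clan_summary(mk_consensus("IGHV1-1", 0.4), ref)
  expect_equal(cs$pct, c(100, 0, 0))
  # clan averages 0.2 / 0.1 / 0.1 -> 50 / 25 / 25
  cs2 <- clan_summary(mk_consensus(
    c("IGHV1-1", "IGHV4-2", "IGHV3-9"), c(0.2, 0.1, 0.1)), ref)
  expect_equal(cs2$pct[cs2$clan == "I"], 50)
  expect_equal(cs2$pct[cs2$clan == "II"], 25)
  expect_equal(cs2$pct[cs2$clan == "III"], 25)
  expect_equal(sum(cs2$pct), 100, tolerance = 1e-9)
  expect_error(clan_summary(mk_consensus("IGHVX", 1), ref))
})

test_that("functionality summary averages per class and rescales to 100", {
  ref <- toy_reference()
  mk_allele_consensus <- function(alleles, means) {
    structure(tibble::tibble(candidate = alleles, mean_score = means,
                             pct_of_total = NA_real_),
              n_voters = 1L, level = "allele", group = "t",
              class = c("towards_consensus", class(tibble::tibble())))
  }
  # only F alleles -> F = 100
  fs <- functionality_summary(
    mk_allele_consensus(c("IGHV1-1*01", "IGHV3-9*01"), c(0.3, 0.1)), ref)
  expect_equal(fs$pct, c(100, 0, 0))
  # class averages 0.3 (F) / 0.3 (P) -> 50/50/0
  fs2 <- functionality_summary(
    mk_allele_consensus(c("IGHV1-1*01", "IGHV4-2*01"), c(0.3, 0.3)), ref)
  expect_equal(fs2$pct, c(50, 50, 0))
  # three classes 0.3/0.3/0.4 via a reference with an ORF allele
  tbl <- as_tibble(toy_reference())[, c("allele", "gene", "subgroup",
                                        "functionality", "orphon",
                                        "partial_5prime", "nt_gapped")]
  tbl$functionality[tbl$allele == "IGHV3-9*01"] <- "ORF"
  ref2 <- ighv_reference(tbl)
  fs3 <- functionality_summary(
    mk_allele_consensus(c("IGHV1-1*01", "IGHV4-2*01", "IGHV3-9*01"),
                        c(0.3, 0.3, 0.4)), ref2)
  expect_equal(fs3$pct, c(30, 30, 40))
})

test_that("subset clustering merges nearest clan profiles first", {
  tbl <- tibble::tibble(
    group = c("s1", "s2", "s3"),
    clan_I = c(100, 0, 99), clan_II = c(0, 100, 1), clan_III = 0)
  hc <- cluster_subsets(tbl)
  # first merge joins s1 and s3 (distance sqrt(2))
  first <- sort(hc$labels[-hc$merge[1, ]])
  expect_equal(first, c("s1", "s3"))

  # identical vectors merge at height zero
  two <- tibble::tibble(group = c("a", "b"), x = 1, y = 2)
  expect_equal(cluster_subsets(two)$height, 0)

  # n subsets -> n - 1 merges
  five <- tibble::tibble(group = paste0("s", 1:5),
                         x = c(1, 2, 10, 11, 30), y = 0)
  expect_equal(nrow(cluster_subsets(five)$merge), 4)
  expect_error(cluster_subsets(two[1, ]), "at least 2")

  # Newick export carries all labels
  nwk <- as_newick(cluster_subsets(five))
  expect_true(all(vapply(paste0("s", 1:5), grepl, logical(1), nwk,
                         fixed = TRUE)))
})
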