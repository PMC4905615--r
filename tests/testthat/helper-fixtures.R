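# Fixtures and independent oracles, all built in code.

# Hand-built toy reference: frame length 12, three genes across the
# three clans, one pseudogene allele.
toy_reference <- function() {
  ighv_reference(tibble::tibble(
    allele = c("IGHV1-1*01", "IGHV1-1*02", "IGHV3-9*01", "IGHV4-2*01"),
    gene = c("IGHV1-1", "IGHV1-1", "IGHV3-9", "IGHV4-2"),
    subgroup = c(1L, 1L, 3L, 4L),
    functionality = c("F", "F", "F", "P"),
    orphon = FALSE,
    partial_5prime = FALSE,
    nt_gapped = c(
      "ACGTACGTACGT",
      "ACGTTCGTACGT",  # differs from *01 at position 5 (A -> T)
      "ACGTACGTACGA",  # differs from IGHV1-1*01 at position 12
      "TCGTACG.ACGT"   # differs at 1, gap at 8
    )
  ), version_label = "toy")
}

# One rearrangement row aligned to the toy 12-position frame.
toy_rearr <- function(sequence_id, v_call, sequence_alignment,
                      productive = TRUE, v_identity = NA_real_,
                      subset = NA_character_,
                      mutations = NULL) {
  if (is.na(v_identity)) {
    v_identity <- pairwise_identity(
      toy_reference()$nt_gapped[match(v_call, toy_reference()$allele)],
      sequence_alignment)
  }
  tibble::tibble(
    sequence_id = sequence_id, productive = productive,
    v_call = v_call, v_identity = v_identity,
    sequence_alignment = sequence_alignment,
    mutations = list(mutations), subset = subset
  )
}

# Independent oracle: brute-force triple loop (sequence x position x
# allele) classifying every substitution as SH / non-SH.
brute_force_scan <- function(rearr, ref, conserved_only = FALSE) {
  bases <- c("A", "C", "G", "T")
  sh <- list()
  nonsh <- list()
  muts <- list()
  for (i in seq_len(nrow(rearr))) {
    sid <- rearr$sequence_id[i]
    sbm_allele <- rearr$v_call[i]
    sbm <- strsplit(ref$nt_gapped[match(sbm_allele, ref$allele)], "")[[1]]
    sam <- strsplit(rearr$sequence_alignment[i], "")[[1]]
    cons <- if (conserved_only) {
      conserved_positions(ref, gene_of_allele(sbm_allele))
    } else {
      seq_along(sbm)
    }
    for (p in seq_along(sbm)) {
      if (!(sbm[p] %in% bases) || !(sam[p] %in% bases)) next
      if (sbm[p] == sam[p]) next
      if (!(p %in% cons)) next
      muts[[length(muts) + 1]] <- data.frame(
        sequence_id = sid, nt_pos = p, from_base = sbm[p],
        to_base = sam[p])
      n_shared <- 0
      for (j in seq_len(nrow(ref))) {
        if (ref$allele[j] == sbm_allele) next
        towg <- strsplit(ref$nt_gapped[j], "")[[1]]
        if (towg[p] %in% bases && towg[p] == sam[p]) {
          n_shared <- n_shared + 1
          sh[[length(sh) + 1]] <- data.frame(
            sequence_id = sid, nt_pos = p, from_base = sbm[p],
            to_base = sam[p], towg_allele = ref$allele[j])
        }
      }
      if (n_shared == 0) {
        nonsh[[length(nonsh) + 1]] <- data.frame(
          sequence_id = sid, nt_pos = p, from_base = sbm[p],
          to_base = sam[p])
      }
    }
  }
  bind_or_empty <- function(x, cols) {
    if (length(x) == 0) {
      return(stats::setNames(
        as.data.frame(replicate(length(cols), character(0),
                                simplify = FALSE)), cols))
    }
    do.call(rbind, x)
  }
  list(
    sh = bind_or_empty(sh, c("sequence_id", "nt_pos", "from_base",
                             "to_base", "towg_allele")),
    nonsh = bind_or_empty(nonsh, c("sequence_id", "nt_pos",
                                   "from_base", "to_base")),
    mutations = bind_or_empty(muts, c("sequence_id", "nt_pos",
                                      "from_base", "to_base"))
  )
}

# Random toy instance for property tests: <= 10 alleles, <= 10
# sequences, <= 8 substitutions each, frame length a small multiple
# of 3, occasional gaps and Ns.
random_instance <- function(seed) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  L <- 3 * sample(5:10, 1)
  n_genes <- sample(2:4, 1)
  rows <- list()
  for (g in seq_len(n_genes)) {
    sg <- sample(1:7, 1)
    gene <- paste0("IGHV", sg, "-", g)
    anc <- sample(bases, L, replace = TRUE)
    if (runif(1) < 0.5) anc[sample.int(L, 1)] <- "."
    n_alleles <- sample(1:3, 1)
    for (a in seq_len(n_alleles)) {
      al <- anc
      if (a > 1) {
        p <- sample(which(al %in% bases), sample(1:2, 1))
        for (q in p) al[q] <- sample(setdiff(bases, al[q]), 1)
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        allele = sprintf("%s*%02d", gene, a), gene = gene,
        subgroup = sg, functionality = sample(c("F", "P", "ORF"), 1),
        orphon = FALSE, partial_5prime = FALSE,
        nt_gapped = paste(al, collapse = ""))
    }
  }
  ref <- ighv_reference(purrr::list_rbind(rows))
  ref <- ref[1:min(10, nrow(ref)), ]
  attr(ref, "frame_length") <- L
  class(ref) <- c("ighv_reference", class(tibble::tibble()))
  n_seq <- sample(1:10, 1)
  rearr <- purrr::list_rbind(purrr::map(seq_len(n_seq), function(i) {
    sbm_allele <- sample(ref$allele, 1)
    ch <- strsplit(ref$nt_gapped[match(sbm_allele, ref$allele)],
                   "")[[1]]
    n_mut <- sample(0:8, 1)
    sites <- sample(which(ch %in% bases),
                    min(n_mut, sum(ch %in% bases)))
    for (p in sites) ch[p] <- sample(setdiff(bases, ch[p]), 1)
    if (runif(1) < 0.3) ch[sample.int(L, 1)] <- "N"
    seq <- paste(ch, collapse = "")
    tibble::tibble(
      sequence_id = sprintf("S%02d", i), productive = TRUE,
      v_call = sbm_allele,
      v_identity = pairwise_identity(
        ref$nt_gapped[match(sbm_allele, ref$allele)], seq),
      sequence_alignment = seq, mutations = list(NULL),
      subset = sample(c("#4", "#201", NA), 1))
  }))
  list(ref = ref, rearr = rearr)
}

# Order a scan component canonically so implementations can be
# compared row for row.
canon <- function(df) {
  df <- as.data.frame(df)
  df$nt_pos <- as.integer(df$nt_pos)
  df[do.call(order, df), , drop = FALSE] |>
    (\(d) {rownames(d) <- NULL; d})()
}

# Build a towards_lists object directly (for unit tests of the
# aggregation chain without running a scan).
manual_scored_lists <- function(voters, level = "gene",
                                conserved_only = FALSE) {
  tbl <- purrr::list_rbind(purrr::imap(voters, function(v, i) {
    tibble::tibble(
      sequence_id = v$id %||% paste0("V", i),
      sbm_allele = v$sbm %||% "IGHV1-1*01",
      subset = v$subset %||% NA_character_,
      m_i = v$m %||% 1L,
      voting = (v$m %||% 1L) > 0,
      elements = list(tibble::tibble(candidate = v$candidates,
                                     score = v$scores)))
  }))
  towardsig:::new_towards_lists(tbl, stage = "scored", level = level,
                                conserved_only = conserved_only)
}

`%||%` <- rlang::`%||%`
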