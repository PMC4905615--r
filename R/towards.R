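# Towards analysis: each patient sequence is a voter; its vote is a
# scored list of candidate towards genes derived from its SH
# mutations. Votes are homogenized, min-max normalized, and combined
# by a Borda-inspired arithmetic-mean aggregation into a consensus
# ranking.

new_towards_lists <- function(tbl, stage, level, conserved_only,
                              homogenized = FALSE, normalized = FALSE) {
  structure(
    tbl,
    stage = stage, level = level, conserved_only = conserved_only,
    homogenized = homogenized, normalized = normalized,
    class = c("towards_lists", class(tibble()))
  )
}

towards_meta <- function(lists) {
  attributes(lists)[c("stage", "level", "conserved_only",
                      "homogenized", "normalized")]
}

#' Build per-sequence raw towards lists from an SH scan
#'
#' One list (row) per patient sequence: the metadata (patient ID, sBm,
#' subset, mutation count `m_i`) plus the list elements, one per
#' towards allele with its SH count. Sequences with `m_i = 0` are
#' flagged non-voting; sequences whose mutations are all non-SH keep
#' an empty element set but remain voters (they contribute zeros after
#' homogenization).
#'
#' @param scan An [sh_scan()] result.
#' @return A `towards_lists` tibble with columns `sequence_id`,
#'   `sbm_allele`, `subset`, `m_i`, `voting` and a list-column
#'   `elements` of tibbles `(allele, sh_count)`.
#' @export
build_raw_lists <- function(scan) {
  counts <- scan$sh %>%
    count(.data$sequence_id, .data$towg_allele, name = "sh_count")
  roster <- scan$sequences
  elements <- map(roster$sequence_id, function(sid) {
    el <- counts[counts$sequence_id == sid, c("towg_allele", "sh_count")]
    tibble(allele = el$towg_allele, sh_count = as.integer(el$sh_count)) %>%
      arrange(.data$allele)
  })
  tbl <- tibble(
    sequence_id = roster$sequence_id,
    sbm_allele = roster$sbm_allele,
    subset = roster$subset,
    m_i = roster$m_i,
    voting = roster$m_i > 0L,
    elements = elements
  )
  new_towards_lists(tbl, stage = "raw", level = "allele",
                    conserved_only = scan$conserved_only)
}

#' Towards score
#'
#' The per-candidate score behind each vote, a product of three
#' factors: the fraction of the available movement achieved
#' (`sh / m`), the fraction of the initial movement capability
#' achieved (`sh / maxsh`), and a selectivity penalty (`1 / selsc`,
#' where `selsc` counts the candidates tied at this SH count):
#' `score = sh^2 / (m * maxsh * selsc)`.
#'
#' @param sh SH mutation count (gene level: mean over the gene's
#'   alleles).
#' @param m Number of mutations in the sequence (the available
#'   movement).
#' @param maxsh Dissimilarity between sBm and the candidate (the
#'   initial movement capability).
#' @param selsc Number of candidates sharing this SH count
#'   (self-inclusive, so at least 1).
#' @return Numeric score(s).
#' @export
towards_score <- function(sh, m, maxsh, selsc) {
  if (any(m <= 0)) abort("towards_score: m must be positive")
  if (any(maxsh <= 0)) abort("towards_score: maxsh must be positive")
  if (any(selsc < 1)) abort("towards_score: selsc must be >= 1")
  (sh * sh) / (m * maxsh * selsc)
}

# Candidate table for one sBm allele: allele, gene, dissimilarity to
# the sBm over compared positions (restricted when conserved_only).
candidate_table <- function(ref, sbm_allele, exclude_sbm_gene,
                            conserved_only) {
  sbm_gene <- gene_of_allele(sbm_allele)
  cand <- ref[ref$allele != sbm_allele, , drop = FALSE]
  if (exclude_sbm_gene) {
    cand <- cand[cand$gene != sbm_gene, , drop = FALSE]
  }
  positions <- if (conserved_only) {
    conserved_positions(ref, sbm_gene)
  } else NULL
  sbm_seq <- ref$nt_gapped[match(sbm_allele, ref$allele)]
  tibble(
    allele = cand$allele,
    gene = cand$gene,
    dissim = map_int(cand$nt_gapped,
                     ~ as.integer(dissimilarity_count(sbm_seq, .x,
                                                      positions)))
  )
}

# selSc by exact rational equality of mean SH counts: two means
# sum_a/n_a and sum_b/n_b are equal iff sum_a * n_b == sum_b * n_a.
# Avoids float ties when genes have different allele counts.
selsc_counts <- function(sh_sum, n_alleles) {
  vapply(seq_along(sh_sum), function(k) {
    sum(sh_sum[k] * n_alleles == sh_sum * n_alleles[k])
  }, integer(1))
}

#' Score towards lists
#'
#' Turns raw SH-count lists into scored lists ready for aggregation.
#' At gene level the SH count of a candidate gene is the arithmetic
#' mean of the SH counts of its alleles (alleles sharing nothing
#' contribute zero), and the initial movement capability is likewise
#' the mean allele dissimilarity to the sBm; at allele level both are
#' per-allele values. Candidates with a zero SH count are omitted
#' (their score is zero); candidates identical to the sBm over the
#' compared positions (zero capability) are dropped with a message.
#' Non-voting sequences (`m_i = 0`) are carried through unscored.
#'
#' @param raw Raw `towards_lists` from [build_raw_lists()].
#' @param ref The filtered [ighv_reference()].
#' @param level `"gene"` (default) or `"allele"`.
#' @param exclude_sbm_gene Exclude all alleles of the sBm gene from
#'   the candidates (default `TRUE`: the analysis studies movement
#'   towards other genes).
#' @return A scored `towards_lists`; each element tibble has columns
#'   `candidate` and `score`.
#' @export
score_lists <- function(raw, ref, level = c("gene", "allele"),
                        exclude_sbm_gene = TRUE) {
  level <- match.arg(level)
  conserved_only <- attr(raw, "conserved_only")
  cand_cache <- list()
  dropped_zero_cap <- 0L
  elements <- map(seq_len(nrow(raw)), function(i) {
    empty <- tibble(candidate = character(), score = double())
    if (!raw$voting[i]) return(empty)
    sbm <- raw$sbm_allele[i]
    if (is.null(cand_cache[[sbm]])) {
      cand_cache[[sbm]] <<- candidate_table(ref, sbm, exclude_sbm_gene,
                                            conserved_only)
    }
    cand <- cand_cache[[sbm]]
    el <- raw$elements[[i]]
    cand$sh <- el$sh_count[match(cand$allele, el$allele)]
    cand$sh[is.na(cand$sh)] <- 0L
    if (level == "gene") {
      by_gene <- cand %>%
        group_by(.data$gene) %>%
        summarise(sh_sum = sum(.data$sh), n_alleles = dplyr::n(),
                  maxsh = mean(.data$dissim), .groups = "drop")
      pos <- by_gene[by_gene$sh_sum > 0, , drop = FALSE]
      if (nrow(pos) == 0) return(empty)
      zero_cap <- pos$maxsh == 0
      dropped_zero_cap <<- dropped_zero_cap + sum(zero_cap)
      pos <- pos[!zero_cap, , drop = FALSE]
      if (nrow(pos) == 0) return(empty)
      selsc <- selsc_counts(pos$sh_sum, pos$n_alleles)
      tibble(
        candidate = pos$gene,
        score = towards_score(pos$sh_sum / pos$n_alleles,
                              raw$m_i[i], pos$maxsh, selsc)
      ) %>% arrange(.data$candidate)
    } else {
      pos <- cand[cand$sh > 0, , drop = FALSE]
      if (nrow(pos) == 0) return(empty)
      zero_cap <- pos$dissim == 0
      dropped_zero_cap <<- dropped_zero_cap + sum(zero_cap)
      pos <- pos[!zero_cap, , drop = FALSE]
      if (nrow(pos) == 0) return(empty)
      selsc <- selsc_counts(pos$sh, rep(1L, nrow(pos)))
      tibble(
        candidate = pos$allele,
        score = towards_score(pos$sh, raw$m_i[i], pos$dissim, selsc)
      ) %>% arrange(.data$candidate)
    }
  })
  if (dropped_zero_cap > 0) {
    inform(paste0("score_lists: dropped ", dropped_zero_cap,
                  " candidate(s) with zero movement capability"))
  }
  tbl <- raw
  tbl$elements <- elements
  new_towards_lists(tbl, stage = "scored", level = level,
                    conserved_only = conserved_only)
}

#' Homogenize scored lists
#'
#' Transforms every list to contain the union of the candidates found
#' across all selected lists, scoring the newly introduced candidates
#' zero, so that aggregation compares like with like. Candidate order
#' is canonical (lexicographic).
#'
#' @param lists Scored `towards_lists`.
#' @return Homogenized `towards_lists`.
#' @export
homogenize_lists <- function(lists) {
  if (nrow(lists) == 0) abort("homogenize_lists: no lists")
  universe <- lex_sort(unique(unlist(map(lists$elements,
                                         ~ .x$candidate))))
  elements <- map(lists$elements, function(el) {
    score <- el$score[match(universe, el$candidate)]
    score[is.na(score)] <- 0
    tibble(candidate = universe, score = score)
  })
  tbl <- lists
  tbl$elements <- elements
  meta <- towards_meta(lists)
  new_towards_lists(tbl, stage = meta$stage, level = meta$level,
                    conserved_only = meta$conserved_only,
                    homogenized = TRUE, normalized = meta$normalized)
}

#' Min-max normalize each list to \[0, 1\]
#'
#' Each voter's scores are rescaled by
#' `(s - s_min) / (s_max - s_min)` over that list, so every voter is
#' an equivalent experiment regardless of its mutation load; the
#' candidate at 1 marks the maximum movement the sBm of that sequence
#' can achieve. Degenerate lists: an all-zero list stays all-zero; a
#' constant nonzero list is set to all ones.
#'
#' @param lists Homogenized `towards_lists`.
#' @return Normalized `towards_lists`.
#' @export
normalize_lists <- function(lists) {
  elements <- map(lists$elements, function(el) {
    if (nrow(el) == 0) return(el)
    lo <- min(el$score)
    hi <- max(el$score)
    el$score <- if (hi > lo) {
      (el$score - lo) / (hi - lo)
    } else if (hi == 0) {
      el$score
    } else {
      rep(1, nrow(el))
    }
    el
  })
  tbl <- lists
  tbl$elements <- elements
  meta <- towards_meta(lists)
  new_towards_lists(tbl, stage = meta$stage, level = meta$level,
                    conserved_only = meta$conserved_only,
                    homogenized = meta$homogenized, normalized = TRUE)
}

#' Aggregate normalized lists into a consensus ranking
#'
#' Borda-inspired aggregation: the consensus score of each candidate
#' is the arithmetic mean of its normalized score across the voting
#' lists. Candidates are ranked by mean score (ties broken
#' lexicographically), and each mean is also expressed as a
#' percentage of the total movement (`pct_of_total`).
#'
#' @param lists Homogenized, normalized `towards_lists`.
#' @param group Optional label for the aggregated group (e.g. a
#'   subset).
#' @return A `towards_consensus`: tibble with columns `candidate`,
#'   `mean_score`, `pct_of_total`, carrying `n_voters`, `level` and
#'   `group` attributes.
#' @export
aggregate_lists <- function(lists, group = NULL) {
  if (!isTRUE(attr(lists, "homogenized")) ||
      !isTRUE(attr(lists, "normalized"))) {
    abort("aggregate_lists: lists must be homogenized and normalized")
  }
  voters <- lists[lists$voting, , drop = FALSE]
  if (nrow(voters) == 0) abort("aggregate_lists: zero voters")
  mat <- do.call(rbind, map(voters$elements, ~ .x$score))
  universe <- voters$elements[[1]]$candidate
  mean_score <- colMeans(mat)
  total <- sum(mean_score)
  out <- tibble(
    candidate = universe,
    mean_score = as.numeric(mean_score),
    pct_of_total = if (total > 0) 100 * mean_score / total else
      rep(0, length(mean_score))
  ) %>%
    arrange(desc(.data$mean_score), .data$candidate)
  structure(out,
            n_voters = nrow(voters),
            level = attr(lists, "level"),
            group = group,
            class = c("towards_consensus", class(tibble())))
}

#' @export
print.towards_consensus <- function(x, n = 10, ...) {
  grp <- attr(x, "group")
  cat("<towards_consensus", if (!is.null(grp)) paste0(" group=", grp),
      "> ", attr(x, "n_voters"), " voters, level=", attr(x, "level"),
      "\n", sep = "")
  NextMethod()
}

#' @rdname aggregate_lists
#' @param x A `towards_consensus`.
#' @param ... Unused.
#' @export
tidy.towards_consensus <- function(x, ...) {
  tibble(
    group = attr(x, "group") %||% NA_character_,
    candidate = x$candidate,
    mean_score = x$mean_score,
    pct_of_total = x$pct_of_total,
    rank = seq_len(nrow(x))
  )
}

#' @rdname aggregate_lists
#' @export
glance.towards_consensus <- function(x, ...) {
  tibble(
    group = attr(x, "group") %||% NA_character_,
    n_voters = attr(x, "n_voters"),
    n_candidates = nrow(x),
    level = attr(x, "level"),
    top_candidate = if (nrow(x) > 0) x$candidate[1] else NA_character_,
    top_pct = if (nrow(x) > 0) x$pct_of_total[1] else NA_real_
  )
}
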