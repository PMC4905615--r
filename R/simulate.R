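# Synthetic data: toy germline references and mutated patient cohorts
# with known ground truth, so every pipeline stage is testable without
# access to patient data or a germline database download.

#' Simulation specification
#'
#' Defines a toy germline reference (alleles per gene, genes per
#' subgroup, subgroups spanning the clans, mixed functionality) and a
#' patient cohort whose mutations are drawn with a configurable bias
#' toward a designated target germline gene.
#'
#' Defaults describe a small but structurally faithful study: a
#' 12-gene reference (3 subgroups x 4 genes, one subgroup per clan,
#' 2 alleles per gene) over the full 312-position gapped V frame, with
#' pseudogene and ORF fractions matching their real share of the IGHV
#' repertoire (roughly 13% P and 4% ORF); a cohort of 30 sequences
#' assigned round-robin to five stereotyped subset labels; a Poisson
#' mutation load with mean 8; and a 0.8 probability that each mutation
#' copies the target germline's base (guaranteeing an SH toward the
#' target) rather than introducing a base found in no germline.
#'
#' @param n_subgroups Number of IGHV subgroups (1..7, taken in order,
#'   so 3 covers all three clans).
#' @param genes_per_subgroup,alleles_per_gene Reference shape.
#' @param seq_len_nt Gapped frame length (multiple of 3, >= 30).
#' @param pseudo_fraction,orf_fraction Expected fractions of P and ORF
#'   alleles; the rest are functional.
#' @param n_sequences Cohort size (voters).
#' @param mutations_per_seq Mean (Poisson) or exact (fixed) number of
#'   mutations per sequence.
#' @param mutation_model `"poisson"` (default) or `"fixed"`.
#' @param target_gene Gene whose sequence biased mutations copy.
#' @param sbm_allele Assigned germline of every simulated sequence;
#'   `NULL` picks the first functional allele outside the target gene.
#' @param bias_p Probability that a mutation copies the target's base.
#' @param subset_labels Stereotyped subset labels assigned round-robin.
#' @param seed Integer seed; everything downstream is deterministic in
#'   it.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(n_subgroups = 3, genes_per_subgroup = 4,
                     alleles_per_gene = 2, seq_len_nt = 312,
                     pseudo_fraction = 0.13, orf_fraction = 0.04,
                     n_sequences = 30, mutations_per_seq = 8,
                     mutation_model = c("poisson", "fixed"),
                     target_gene = "IGHV2-1", sbm_allele = NULL,
                     bias_p = 0.8,
                     subset_labels = c("#4", "#11", "#16", "#29", "#201"),
                     seed = 1) {
  mutation_model <- match.arg(mutation_model)
  if (n_subgroups < 1 || n_subgroups > 7) {
    abort("n_subgroups must be in 1..7")
  }
  if (genes_per_subgroup < 1 || alleles_per_gene < 1) {
    abort("need at least one gene per subgroup and one allele per gene")
  }
  if (seq_len_nt < 30 || seq_len_nt %% 3 != 0) {
    abort("seq_len_nt must be a multiple of 3 and at least 30")
  }
  if (pseudo_fraction < 0 || orf_fraction < 0 ||
      pseudo_fraction + orf_fraction > 1) {
    abort("pseudo_fraction and orf_fraction must be fractions summing to <= 1")
  }
  if (bias_p < 0 || bias_p > 1) abort("bias_p must be in [0, 1]")
  structure(
    list(n_subgroups = as.integer(n_subgroups),
         genes_per_subgroup = as.integer(genes_per_subgroup),
         alleles_per_gene = as.integer(alleles_per_gene),
         seq_len_nt = as.integer(seq_len_nt),
         pseudo_fraction = pseudo_fraction, orf_fraction = orf_fraction,
         n_sequences = as.integer(n_sequences),
         mutations_per_seq = mutations_per_seq,
         mutation_model = mutation_model,
         target_gene = target_gene, sbm_allele = sbm_allele,
         bias_p = bias_p, subset_labels = subset_labels,
         seed = as.integer(seed)),
    class = "sim_spec"
  )
}

# Fraction of each gene's columns turned into gap placeholders and
# number of positions at which each extra allele diverges from its
# gene's ancestor (gives every multi-allele gene both conserved and
# non-conserved columns).
SIM_GAP_FRACTION <- 0.02
SIM_ALLELE_DIVERGENCE <- 4L

#' Simulate a toy germline reference
#'
#' Genes are built from a per-gene random ancestor; additional alleles
#' mutate the ancestor at a few positions, so genes carry both
#' conserved and non-conserved columns. A small fraction of columns
#' per gene become IMGT-style gap placeholders shared by the gene's
#' alleles. Functionality is assigned allele-wise from the configured
#' fractions. Deterministic in `spec$seed`.
#'
#' @param spec A [sim_spec()].
#' @return An [ighv_reference()].
#' @export
simulate_reference <- function(spec) {
  withr::local_seed(spec$seed)
  rows <- list()
  for (sg in seq_len(spec$n_subgroups)) {
    for (g in seq_len(spec$genes_per_subgroup)) {
      gene <- paste0("IGHV", sg, "-", g)
      anc <- sample(DNA_BASES, spec$seq_len_nt, replace = TRUE)
      n_gap <- round(SIM_GAP_FRACTION * spec$seq_len_nt)
      if (n_gap > 0) {
        anc[sample.int(spec$seq_len_nt, n_gap)] <- "."
      }
      base_pos <- which(anc %in% DNA_BASES)
      for (a in seq_len(spec$alleles_per_gene)) {
        al <- anc
        if (a > 1) {
          div <- sample(base_pos,
                        min(SIM_ALLELE_DIVERGENCE, length(base_pos)))
          for (p in div) {
            al[p] <- sample(setdiff(DNA_BASES, al[p]), 1)
          }
        }
        fun <- sample(c("P", "ORF", "F"), 1,
                      prob = c(spec$pseudo_fraction, spec$orf_fraction,
                               1 - spec$pseudo_fraction - spec$orf_fraction))
        rows[[length(rows) + 1L]] <- tibble(
          allele = sprintf("%s*%02d", gene, a),
          gene = gene, subgroup = sg, functionality = fun,
          orphon = FALSE, partial_5prime = FALSE,
          nt_gapped = paste(al, collapse = "")
        )
      }
    }
  }
  ighv_reference(list_rbind(rows),
                 version_label = paste0("sim-seed", spec$seed))
}

#' Simulate a mutated patient cohort with known ground truth
#'
#' Every sequence starts from the chosen sBm allele. Each mutation
#' site is drawn, with probability `bias_p`, uniformly over the
#' positions where the sBm and the target allele differ, introducing
#' the target's base (a guaranteed SH toward the target); otherwise a
#' position and base are drawn so that no reference germline carries
#' that base at that column (a guaranteed non-SH), re-drawing the
#' position when every alternative base at a column exists in some
#' germline. Each position mutates at most once per sequence. The
#' truth manifest records every planted mutation and its type.
#'
#' @param ref The simulated [ighv_reference()].
#' @param spec The [sim_spec()] used (its `target_gene` must be in
#'   `ref`).
#' @return A `sim_cohort` list: `rearrangements` (tibble in the
#'   [read_rearrangements()] layout), `subsets` (patient to subset),
#'   `truth` (one row per planted mutation: `sequence_id`, `nt_pos`,
#'   `from_base`, `to_base`, `planted` of `"sh_target"`/`"nonsh"`),
#'   and `params` (sBm and target alleles, seed).
#' @export
simulate_cohort <- function(ref, spec) {
  withr::local_seed(spec$seed + 1L)
  target_alleles <- lex_sort(ref$allele[ref$gene == spec$target_gene])
  if (length(target_alleles) == 0) {
    abort(paste0("target_gene not in reference: ", spec$target_gene))
  }
  target <- target_alleles[1]
  sbm <- spec$sbm_allele %||% {
    cand <- lex_sort(ref$allele[ref$functionality == "F" &
                                  ref$gene != spec$target_gene])
    if (length(cand) == 0) abort("no eligible sBm allele outside target gene")
    cand[1]
  }
  if (!sbm %in% ref$allele) {
    abort(paste0("sbm_allele not in reference: ", sbm))
  }
  sbm_ch <- seq_chars(ref$nt_gapped[match(sbm, ref$allele)])
  tgt_ch <- seq_chars(ref$nt_gapped[match(target, ref$allele)])
  diff_pos <- which(sbm_ch %in% DNA_BASES & tgt_ch %in% DNA_BASES &
                      sbm_ch != tgt_ch)
  if (spec$bias_p > 0 && length(diff_pos) == 0) {
    abort("bias_p > 0 but sBm and target are identical over compared positions")
  }
  ref_m <- reference_matrix(ref)
  base_pos <- which(sbm_ch %in% DNA_BASES)
  # bases absent from every germline at each column of the frame
  absent_bases <- map(seq_along(sbm_ch),
                      ~ setdiff(DNA_BASES, ref_m[, .x]))
  rearr_rows <- list()
  truth_rows <- list()
  for (i in seq_len(spec$n_sequences)) {
    sid <- sprintf("P%03d", i)
    n_mut <- if (spec$mutation_model == "poisson") {
      rpois(1, spec$mutations_per_seq)
    } else {
      as.integer(spec$mutations_per_seq)
    }
    seq_ch <- sbm_ch
    free_diff <- diff_pos
    free_any <- base_pos
    planted <- list()
    for (k in seq_len(n_mut)) {
      biased <- runif(1) < spec$bias_p && length(free_diff) > 0
      if (biased) {
        pos <- free_diff[sample.int(length(free_diff), 1)]
        to <- tgt_ch[pos]
        type <- "sh_target"
      } else {
        pos <- NA_integer_
        to <- NA_character_
        pool <- free_any
        while (length(pool) > 0) {
          p <- pool[sample.int(length(pool), 1)]
          avail <- setdiff(absent_bases[[p]], seq_ch[p])
          if (length(avail) > 0) {
            pos <- p
            to <- avail[sample.int(length(avail), 1)]
            break
          }
          pool <- setdiff(pool, p)
        }
        if (is.na(pos)) {
          abort("cannot place a non-SH mutation: every base occurs in some germline at every remaining column")
        }
        type <- "nonsh"
      }
      planted[[length(planted) + 1L]] <- tibble(
        sequence_id = sid, nt_pos = as.integer(pos),
        from_base = sbm_ch[pos], to_base = to, planted = type
      )
      seq_ch[pos] <- to
      free_diff <- setdiff(free_diff, pos)
      free_any <- setdiff(free_any, pos)
    }
    seq_str <- paste(seq_ch, collapse = "")
    muts <- if (length(planted) > 0) {
      list_rbind(planted) %>% arrange(.data$nt_pos) %>%
        select("nt_pos", "from_base", "to_base")
    } else {
      tibble(nt_pos = integer(), from_base = character(),
             to_base = character())
    }
    rearr_rows[[i]] <- tibble(
      sequence_id = sid, productive = TRUE, v_call = sbm,
      v_identity = pairwise_identity(
        ref$nt_gapped[match(sbm, ref$allele)], seq_str),
      sequence_alignment = seq_str,
      mutations = list(muts),
      subset = NA_character_
    )
    if (length(planted) > 0) {
      truth_rows[[length(truth_rows) + 1L]] <- list_rbind(planted)
    }
  }
  k <- length(spec$subset_labels)
  subsets <- tibble(
    patient_id = sprintf("P%03d", seq_len(spec$n_sequences)),
    subset = spec$subset_labels[((seq_len(spec$n_sequences) - 1L) %% k) + 1L]
  )
  truth <- if (length(truth_rows) > 0) list_rbind(truth_rows) else
    tibble(sequence_id = character(), nt_pos = integer(),
           from_base = character(), to_base = character(),
           planted = character())
  structure(
    list(rearrangements = list_rbind(rearr_rows),
         subsets = subsets, truth = truth,
         params = list(sbm_allele = sbm, target_allele = target,
                       target_gene = spec$target_gene,
                       seed = spec$seed)),
    class = "sim_cohort"
  )
}

#' Write a simulated cohort to disk
#'
#' Emits exactly the dialects the loaders consume: the rearrangement
#' TSV, the patient-to-subset TSV, and the truth manifest as JSON.
#'
#' @param cohort A `sim_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    rearrangements = file.path(dir, "rearrangements.tsv"),
    subsets = file.path(dir, "subsets.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_rearrangements(cohort$rearrangements, paths[["rearrangements"]])
  readr::write_tsv(cohort$subsets, paths[["subsets"]])
  jsonlite::write_json(
    list(params = cohort$params, truth = cohort$truth),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
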