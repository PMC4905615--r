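# Consensus summaries: expected movement per clan, per functionality
# class, and hierarchical clustering of groups by their clan profiles.

rescale_to_100 <- function(x) {
  total <- sum(x)
  if (total > 0) 100 * x / total else rep(0, length(x))
}

#' Expected movement per clan
#'
#' Summarises a gene-level consensus into the three IGHV clans: the
#' clan value is the average (or, with `mode = "sum"`, the sum) of the
#' consensus mean scores of that clan's genes, and the three clan
#' values are rescaled to percentages summing to 100.
#'
#' @param consensus A gene-level `towards_consensus`.
#' @param ref The [ighv_reference()] (maps genes to clans).
#' @param mode `"avg"` (default) or `"sum"`.
#' @return Tibble with columns `clan` (`"I"`, `"II"`, `"III"`) and
#'   `pct`.
#' @export
clan_summary <- function(consensus, ref, mode = c("avg", "sum")) {
  mode <- match.arg(mode)
  if (!identical(attr(consensus, "level"), "gene")) {
    abort("clan_summary needs a gene-level consensus")
  }
  gene_clan <- distinct(as_tibble(ref)[, c("gene", "clan")])
  clan <- gene_clan$clan[match(consensus$candidate, gene_clan$gene)]
  if (anyNA(clan)) {
    abort(paste0("gene(s) with unknown clan: ",
                 paste(consensus$candidate[is.na(clan)], collapse = ", ")))
  }
  agg <- if (mode == "avg") mean else sum
  per_clan <- vapply(c("I", "II", "III"), function(cl) {
    v <- consensus$mean_score[clan == cl]
    if (length(v) == 0) 0 else agg(v)
  }, double(1))
  tibble(clan = c("I", "II", "III"),
         pct = unname(rescale_to_100(per_clan)))
}

#' Expected movement per functionality class
#'
#' Summarises an allele-level consensus into the three germline
#' functionality classes (functional F, pseudogene P, open reading
#' frame ORF): the class value is the average (or sum) of the
#' consensus mean scores over that class's alleles, rescaled so the
#' three classes total 100. Averaging accounts for the much larger
#' number of functional alleles, making the movements comparable.
#'
#' @param consensus An allele-level `towards_consensus`.
#' @param ref The [ighv_reference()] (maps alleles to functionality).
#' @param mode `"avg"` (default) or `"sum"`.
#' @return Tibble with columns `functionality` (`"F"`, `"P"`,
#'   `"ORF"`) and `pct`.
#' @export
functionality_summary <- function(consensus, ref,
                                  mode = c("avg", "sum")) {
  mode <- match.arg(mode)
  if (!identical(attr(consensus, "level"), "allele")) {
    abort("functionality_summary needs an allele-level consensus")
  }
  fun <- ref$functionality[match(consensus$candidate, ref$allele)]
  if (anyNA(fun)) {
    abort(paste0("allele(s) with unknown functionality: ",
                 paste(consensus$candidate[is.na(fun)], collapse = ", ")))
  }
  agg <- if (mode == "avg") mean else sum
  per_fun <- vapply(c("F", "P", "ORF"), function(cl) {
    v <- consensus$mean_score[fun == cl]
    if (length(v) == 0) 0 else agg(v)
  }, double(1))
  tibble(functionality = c("F", "P", "ORF"),
         pct = unname(rescale_to_100(per_fun)))
}

#' Cluster groups by their clan movement profiles
#'
#' Hierarchical agglomerative clustering of groups (e.g. stereotyped
#' subsets), each represented by its vector of clan movement
#' percentages. Distance and linkage default to Euclidean / average.
#'
#' @param clan_tbl Long tibble with columns `group`, `clan`, `pct`
#'   (as assembled by [towards_analysis()]), or a wide data frame
#'   with a `group` column and one numeric column per clan.
#' @param metric Distance metric passed to [stats::dist()].
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return An [stats::hclust] tree labelled by group.
#' @export
cluster_subsets <- function(clan_tbl, metric = "euclidean",
                            linkage = "average") {
  if (all(c("clan", "pct") %in% names(clan_tbl))) {
    wide <- tidyr::pivot_wider(clan_tbl, id_cols = "group",
                               names_from = "clan", values_from = "pct")
  } else {
    wide <- clan_tbl
  }
  if (nrow(wide) < 2) abort("cluster_subsets: need at least 2 groups")
  m <- as.matrix(wide[, setdiff(names(wide), "group"), drop = FALSE])
  rownames(m) <- wide$group
  hclust(dist(m, method = metric), method = linkage)
}

#' Serialize a cluster tree as Newick
#'
#' @param hc An [stats::hclust] tree (e.g. from [cluster_subsets()]).
#' @param path Optional file to write to.
#' @return The Newick string, invisibly if written to a file.
#' @export
as_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Run the full towards analysis per group
#'
#' Orchestrates the analysis for a set of filtered, integrated
#' rearrangements: SH scan, raw lists, gene- and allele-level scoring,
#' then per group (by default per stereotyped subset) homogenization,
#' normalization, aggregation, and the clan and functionality
#' summaries; with two or more groups the clan profiles are also
#' clustered.
#'
#' @param rearr Filtered rearrangement tibble.
#' @param ref Filtered [ighv_reference()].
#' @param group_by Grouping column, `"subset"` (default) or `NULL` for
#'   one pooled group labelled `"all"`.
#' @param conserved_only Restrict to conserved gene areas.
#' @param exclude_sbm_gene Exclude the sBm gene from candidates.
#' @param region_restriction Optional IMGT region name.
#' @param clan_mode,functionality_mode `"avg"` or `"sum"` summary
#'   modes.
#' @param linkage Linkage for [cluster_subsets()].
#' @return A `towards_analysis` object: list with `consensus` and
#'   `allele_consensus` (named lists of `towards_consensus` per
#'   group), `clan` and `functionality` (long tibbles), `tree`
#'   (hclust or `NULL`), `scan`, and the parameters.
#' @export
towards_analysis <- function(rearr, ref, group_by = "subset",
                             conserved_only = FALSE,
                             exclude_sbm_gene = TRUE,
                             region_restriction = NULL,
                             clan_mode = c("avg", "sum"),
                             functionality_mode = c("avg", "sum"),
                             linkage = "average") {
  clan_mode <- match.arg(clan_mode)
  functionality_mode <- match.arg(functionality_mode)
  scan <- sh_scan(rearr, ref, conserved_only = conserved_only,
                  region_restriction = region_restriction)
  raw <- build_raw_lists(scan)
  gene_lists <- score_lists(raw, ref, level = "gene",
                            exclude_sbm_gene = exclude_sbm_gene)
  allele_lists <- score_lists(raw, ref, level = "allele",
                              exclude_sbm_gene = exclude_sbm_gene)
  groups <- if (is.null(group_by)) {
    rep("all", nrow(raw))
  } else {
    as.character(raw[[group_by]])
  }
  labels <- lex_sort(unique(groups[!is.na(groups) & raw$voting]))
  if (length(labels) == 0) {
    abort("towards_analysis: no voting sequences in any group")
  }
  one_group <- function(lists, label) {
    sel <- lists[!is.na(groups) & groups == label, , drop = FALSE]
    sel <- new_towards_lists(sel, attr(lists, "stage"),
                             attr(lists, "level"),
                             attr(lists, "conserved_only"))
    sel %>% homogenize_lists() %>% normalize_lists() %>%
      aggregate_lists(group = label)
  }
  consensus <- setNames(map(labels, ~ one_group(gene_lists, .x)), labels)
  allele_consensus <- setNames(map(labels, ~ one_group(allele_lists, .x)),
                               labels)
  clan <- imap(consensus, function(cr, label) {
    mutate(clan_summary(cr, ref, mode = clan_mode),
           group = label, .before = 1)
  }) %>% list_rbind()
  functionality <- imap(allele_consensus, function(cr, label) {
    mutate(functionality_summary(cr, ref, mode = functionality_mode),
           group = label, .before = 1)
  }) %>% list_rbind()
  tree <- if (length(labels) >= 2) {
    cluster_subsets(clan, linkage = linkage)
  } else NULL
  structure(
    list(consensus = consensus, allele_consensus = allele_consensus,
         clan = clan, functionality = functionality, tree = tree,
         scan = scan,
         params = list(group_by = group_by,
                       conserved_only = conserved_only,
                       exclude_sbm_gene = exclude_sbm_gene,
                       region_restriction = region_restriction,
                       clan_mode = clan_mode,
                       functionality_mode = functionality_mode,
                       linkage = linkage)),
    class = "towards_analysis"
  )
}

#' @export
print.towards_analysis <- function(x, ...) {
  cat("<towards_analysis> groups:",
      paste(names(x$consensus), collapse = ", "), "\n")
  cat("  voters per group:",
      paste(map_int(x$consensus, ~ attr(.x, "n_voters")),
            collapse = ", "), "\n")
  cat("  conserved_only:", x$params$conserved_only, "\n")
  invisible(x)
}

#' @rdname towards_analysis
#' @param x A `towards_analysis`.
#' @param ... Unused.
#' @export
tidy.towards_analysis <- function(x, ...) {
  list_rbind(map(x$consensus, tidy))
}

#' @rdname towards_analysis
#' @export
glance.towards_analysis <- function(x, ...) {
  list_rbind(map(x$consensus, glance))
}
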