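---
title: "Shared hypermutations and the towards analysis: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shared hypermutations and the towards analysis: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(towardsig)
```

## The model

Human IGHV germline genes are organised hierarchically: alleles belong
to genes, genes to subgroups 1–7 (the digit after "IGHV" in the
nomenclature), and subgroups to three clans — subgroups 1, 5, 7 form
clan I, subgroups 2, 4, 6 clan II, and subgroup 3 clan III. A
rearranged patient sequence (*sAm*) is aligned to its closest germline
allele (*sBm*) in the IMGT-gapped frame, in which positions are
comparable across genes because `.` placeholders pad every V region
to a common coordinate system.

A nucleotide substitution introduced by somatic hypermutation is
**shared** (SH) with another germline when that germline carries the
introduced base at the same gapped position; the germline is then a
*towards germline* (TowG), because the mutation has locally increased
the sequence's similarity to it. A substitution whose new base occurs
in no germline at that column is **non-SH**. Only substitutions are
modelled: insertions and deletions are rare in SHM and are out of
scope, and positions where either sequence has a gap or an `N` are
skipped. Sharing is intrinsically relational — a mutation is only SH
*with respect to* a TowG — which is why the scan emits one record per
(mutation, TowG) pair.

## The voting scheme

Each sequence is one voter. Its raw vote lists, per towards allele,
the number of SH mutations shared with it. Votes are turned into
gene-level scored lists and aggregated:

1. **Scoring.** For candidate gene $k$ and voter $i$:
   $$\mathrm{score}_{ik} = \frac{SH_{ik} \cdot SH_{ik}}
   {M_i \cdot maxSH_k \cdot selSc_k}$$
   $SH_{ik}$ is the arithmetic mean of the SH counts over the gene's
   alleles (alleles sharing nothing contribute zero), which prevents
   many-allele genes from dominating. $M_i$ is the voter's mutation
   count, so $SH_{ik}/M_i$ is the fraction of the *available*
   movement achieved. $maxSH_k$ is the mean dissimilarity between the
   sBm and the gene's alleles over doubly-covered positions — the
   *initial movement capability* — so $SH_{ik}/maxSH_k$ is the
   fraction of that capability achieved. $selSc_k$ counts the
   candidate genes tied at exactly this SH count (itself included),
   penalising unselective movement.
2. **Homogenizing.** All selected lists are extended to the union of
   their genes, new entries scored zero, in lexicographic order so
   output is byte-stable.
3. **Normalizing.** Each list is min–max scaled to $[0,1]$:
   $s' = (s - s_{\min})/(s_{\max} - s_{\min})$. Every voter thereby
   counts equally regardless of mutation load; the candidate at 1 is
   the maximum movement that voter can express.
4. **Aggregating.** The consensus score of a gene is the arithmetic
   mean of its normalized scores across voters (a Borda-style
   aggregation with scores in place of ranks). Consensus scores are
   also expressed as percentages of the summed consensus — the
   percentage movement per gene.

Clan and functionality summaries average the consensus scores over
each clan's genes (or, for functionality, over each class's alleles
from an allele-level run) and rescale the three class values to sum
to 100. Averaging rather than summing keeps the classes comparable
despite very different sizes — there are far more functional alleles
than pseudogenes. Both `avg` (default) and `sum` modes are exposed,
since summed-score percentages are an equally defensible reading of
"expected movement"; the default follows the class-average
definition.

## Parameters that matter

| parameter | where | default | why |
|---|---|---|---|
| `exclude_sbm_gene` | `score_lists()` | `TRUE` | the question is movement toward *other* genes; sibling alleles of the sBm gene remain visible at allele level and can be included for exploration |
| `conserved_only` | `sh_scan()` | `FALSE` | restricting to positions where all of the sBm gene's alleles agree separates gene-level from allele-specific effects |
| `region_restriction` | filters / scan | none | IMGT spans FR1 1–78, CDR1 79–114, FR2 115–165, CDR2 166–195, FR3 196–312 |
| hotspot motifs | `annotate_mutations()` | RGYW, WRCY, WA, TW | the canonical AID/pol-η SHM hotspots, matched with IUPAC wildcards on the ungapped germline context; a mutation anywhere inside a match window is flagged |
| `clan_mode` / `functionality_mode` | summaries | `avg` | see above |
| linkage / metric | `cluster_subsets()` | average / Euclidean | genuinely open choice; any reasonable pair works on 3-vector clan profiles, and both are configurable |

## Numerical choices

* Tie detection for $selSc_k$ compares SH means as exact rationals
  (integer cross-multiplication of `sum/count` fractions), never as
  floating-point doubles, so equal means are recognised exactly.
* Candidates with $maxSH_k = 0$ (indistinguishable from the sBm over
  the compared positions) would divide by zero; they are dropped with
  a message.
* Degenerate normalization: an all-zero list stays all-zero (a voter
  whose mutations are all non-SH still votes, contributing zeros
  after homogenization); a constant nonzero list becomes all ones.
* Ranked output breaks score ties lexicographically by candidate
  name, with locale-independent (radix) ordering, so repeated runs
  are byte-identical.
* Pairwise identity and dissimilarity are computed over positions
  where both sequences carry a base; gaps and `N` count in neither
  numerator nor denominator, which also handles germlines truncated
  at the 3' end.
* Every sequence must carry a distinct `sequence_id`: all joins key
  on it, and a duplicated id would silently merge two voters. A
  patient with several sequences gets one id per sequence.

## What the generator emulates — and what it does not

`simulate_reference()` builds each gene from a random ancestor,
diverges extra alleles at a handful of positions (so conserved and
non-conserved columns both exist), inserts ~2 % gap columns per gene,
and assigns functionality with pseudogene/ORF fractions of 0.13/0.04
— the approximate proportions in the curated human IGHV repertoire
(about 234 F / 38 P / 12 ORF alleles). `simulate_cohort()` mutates a
fixed sBm allele with a Poisson(8) load; each mutation either copies
the target allele's base (probability `bias_p`, default 0.8 — a
strong, unambiguous planted signal) or introduces a base absent from
every germline at that column. If a biased draw finds no remaining
sBm/target difference it falls back to a non-SH placement; if no
column admits a non-SH base the generator stops with an error rather
than silently planting an unintended sharing. The truth manifest
lists every planted mutation, so the scan can be reconciled against
it exactly.

The generator does **not** emulate real SHM: no hotspot targeting, no
selection, no clonal lineages, no indels, and mutations independent
across positions. Passing the planted-bias test therefore shows that
the pipeline *recovers a known signal through the full scoring and
aggregation chain*, not that real repertoires behave this way.

Default problem sizes (12 genes × 2 alleles over a 312-nt frame,
30-voter cohorts, 50-replicate recovery sweeps) keep a full test run
in the low minutes on a single core while leaving the planted signal
realistic; they are the package's reference study conditions, stated
here once and used unchanged by the tests and the acceptance script.

## Known limitations

* Only IGHV; no D/J genes, no light chains, no junction/CDR3
  analysis.
* The non-SH dataset's `new_property_functionality` column — the
  functionality classes of germlines whose amino acid at that codon
  shares the new residue's chemical class — is an interpretation of
  "where the new property can be found", and is documented as such.
* The GSHD is fixed at 8 columns by including patient id and subset
  alongside the six pair-level features; likewise the SHPD's
  34-column layout is this package's canonical ordering of the
  documented content.
* Aggregation alternatives (Kemeny, Markov-chain rank aggregation)
  and significance testing of between-subset differences are not
  implemented.

## A complete run

```{r, eval = FALSE}
spec   <- sim_spec(n_sequences = 40, seed = 42)
ref    <- simulate_reference(spec)
cohort <- simulate_cohort(ref, spec)
rearr  <- integrate_subsets(cohort$rearrangements, cohort$subsets)

res <- towards_analysis(rearr, ref)
tidy(res)                      # per-subset consensus, long form
plot_clan_movement(res$clan)
as_newick(res$tree)
```
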