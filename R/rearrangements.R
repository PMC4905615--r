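# Rearrangement records: one row per patient sequence (sAm), carrying
# the closest germline V allele (sBm), germline identity, the
# IMGT-gapped sequence, and optionally a pre-computed mutation list.

REARR_REQUIRED_COLS <- c("sequence_id", "productive", "v_call",
                         "v_identity", "sequence_alignment")

MUTATION_TOKEN_RE <- "^[acgt][0-9]+[acgt]$"

parse_productive <- function(x) {
  up <- toupper(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[up %in% c("T", "TRUE", "PRODUCTIVE", "1")] <- TRUE
  out[up %in% c("F", "FALSE", "UNPRODUCTIVE", "0")] <- FALSE
  out
}

# "a78g,c120t" -> tibble(nt_pos, from_base, to_base). Malformed tokens
# raise a condition the loader collects per row.
parse_mutation_tokens <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) {
    return(tibble(nt_pos = integer(), from_base = character(),
                  to_base = character()))
  }
  tokens <- trimws(strsplit(x, ",", fixed = TRUE)[[1]])
  bad <- tokens[!grepl(MUTATION_TOKEN_RE, tokens)]
  if (length(bad) > 0) {
    abort(paste0("malformed mutation token(s): ",
                 paste(bad, collapse = ", ")))
  }
  tibble(
    nt_pos = as.integer(gsub("[acgt]", "", tokens)),
    from_base = toupper(substr(tokens, 1, 1)),
    to_base = toupper(substring(tokens, nchar(tokens)))
  )
}

format_mutation_tokens <- function(muts) {
  if (is.null(muts) || nrow(muts) == 0) return("")
  paste0(tolower(muts$from_base), muts$nt_pos, tolower(muts$to_base),
         collapse = ",")
}

#' Read a rearrangement table
#'
#' Reads a minimal AIRR-compatible TSV with one row per patient
#' sequence. Required columns: `sequence_id` (doubles as the patient
#' unique ID), `productive`, `v_call` (closest germline V allele, the
#' sBm), `v_identity` (germline identity, percent), and
#' `sequence_alignment` (IMGT-gapped nucleotide sequence over
#' `A,C,G,T,N,.`). An optional `mutation_list` column carries tokens of
#' the form `a78g` (from-base, 1-based gapped position, to-base).
#'
#' Rows whose mutation list or sequence fails to parse are dropped and
#' recorded in the load report (see [load_report()]); structural
#' problems (a missing required column) are hard errors.
#'
#' @param path Path to the TSV file.
#' @return A tibble of rearrangements with a `mutations` list-column
#'   and a `subset` column (`NA` until [integrate_subsets()] fills it),
#'   plus a `load_report` attribute.
#' @export
read_rearrangements <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  missing <- setdiff(REARR_REQUIRED_COLS, names(tbl))
  if (length(missing) > 0) {
    abort(paste0("rearrangement table is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  has_mut <- "mutation_list" %in% names(tbl)
  problems <- list()
  rows <- vector("list", nrow(tbl))
  for (i in seq_len(nrow(tbl))) {
    row <- tbl[i, ]
    prod <- parse_productive(row$productive)
    gi <- suppressWarnings(as.numeric(row$v_identity))
    seq <- toupper(row$sequence_alignment)
    issue <- NULL
    muts <- NULL
    if (is.na(prod)) {
      issue <- paste0("unrecognised productive value: ", row$productive)
    } else if (is.na(gi) || gi < 0 || gi > 100) {
      issue <- paste0("v_identity outside [0,100]: ", row$v_identity)
    } else if (grepl("[^ACGTN.]", seq)) {
      issue <- "sequence_alignment has characters outside {A,C,G,T,N,.}"
    } else if (has_mut) {
      muts <- tryCatch(parse_mutation_tokens(row$mutation_list),
                       error = function(e) conditionMessage(e))
      if (is.character(muts)) {
        issue <- muts
        muts <- NULL
      }
    }
    if (!is.null(issue)) {
      problems[[length(problems) + 1L]] <-
        tibble(sequence_id = row$sequence_id, problem = issue)
      rows[[i]] <- NULL
      next
    }
    rows[[i]] <- tibble(
      sequence_id = row$sequence_id,
      productive = prod,
      v_call = row$v_call,
      v_identity = gi,
      sequence_alignment = seq,
      mutations = list(muts),
      subset = NA_character_
    )
  }
  out <- list_rbind(keep(rows, ~ !is.null(.x)))
  if (nrow(out) == 0) {
    out <- tibble(sequence_id = character(), productive = logical(),
                  v_call = character(), v_identity = double(),
                  sequence_alignment = character(), mutations = list(),
                  subset = character())
  }
  report <- if (length(problems) > 0) list_rbind(problems) else
    tibble(sequence_id = character(), problem = character())
  if (nrow(report) > 0) {
    warn(paste0("read_rearrangements: ", nrow(report),
                " row(s) dropped; see load_report()"))
  }
  attr(out, "load_report") <- report
  out
}

#' Row-level problems collected while loading a rearrangement table
#'
#' @param x The tibble returned by [read_rearrangements()].
#' @return A tibble with columns `sequence_id` and `problem`.
#' @export
load_report <- function(x) {
  attr(x, "load_report") %||%
    tibble(sequence_id = character(), problem = character())
}

#' Write a rearrangement table
#'
#' Inverse of [read_rearrangements()]: serialises the `mutations`
#' list-column back into `a78g`-style tokens.
#'
#' @param rearr Rearrangement tibble.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_rearrangements <- function(rearr, path) {
  rearr %>%
    mutate(
      productive = ifelse(.data$productive, "T", "F"),
      mutation_list = map_chr(.data$mutations,
                              ~ format_mutation_tokens(.x))
    ) %>%
    select("sequence_id", "productive", "v_call", "v_identity",
           "sequence_alignment", "mutation_list") %>%
    readr::write_tsv(path)
  invisible(path)
}

#' Read the patient-to-subset assignment table
#'
#' Two-column TSV (`patient_id`, `subset`) from the clinicobiological
#' database mapping patients to stereotyped subsets (e.g. `#4`).
#' Consistent duplicates are collapsed; conflicting assignments are an
#' error.
#'
#' @param path Path to the TSV file.
#' @return Tibble with columns `patient_id`, `subset`.
#' @export
read_subsets <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  missing <- setdiff(c("patient_id", "subset"), names(tbl))
  if (length(missing) > 0) {
    abort(paste0("subset table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  tbl <- distinct(tbl, .data$patient_id, .data$subset)
  dup <- tbl$patient_id[duplicated(tbl$patient_id)]
  if (length(dup) > 0) {
    abort(paste0("conflicting subset assignment for patient(s): ",
                 paste(unique(dup), collapse = ", ")))
  }
  if (nrow(tbl) == 0) warn("read_subsets: empty subset table")
  tbl
}

#' Attach subset labels to rearrangements by patient unique ID
#'
#' The patient unique ID is the join key between the sequence-level
#' data and the clinicobiological subset assignments. Records without
#' an assignment keep `subset = NA`; order and record count are
#' preserved.
#'
#' @param rearr Rearrangement tibble ([read_rearrangements()]).
#' @param subsets Subset tibble ([read_subsets()]).
#' @return `rearr` with the `subset` column filled where known.
#' @export
integrate_subsets <- function(rearr, subsets) {
  idx <- match(rearr$sequence_id, subsets$patient_id)
  out <- mutate(rearr, subset = subsets$subset[idx])
  unused <- sum(!subsets$patient_id %in% rearr$sequence_id)
  if (unused > 0) {
    inform(paste0("integrate_subsets: ", unused,
                  " subset assignment(s) matched no rearrangement"))
  }
  attr(out, "load_report") <- attr(rearr, "load_report")
  out
}
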