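# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# Split a sequence string into a character vector of single characters.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

is_base <- function(ch) ch %in% DNA_BASES

# Locale-independent sort so ranked outputs are byte-stable across platforms.
lex_sort <- function(x) sort(x, method = "radix")

lex_order <- function(x) order(x, method = "radix")

# ceiling(nt_pos / 3) without floating point.
codon_of <- function(nt_pos) (as.integer(nt_pos) + 2L) %/% 3L

stop_stage <- function(stage, msg) {
  abort(paste0(stage, ": ", msg), class = "towardsig_error")
}
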