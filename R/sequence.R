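STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Construct a codon sequence
#'
#' @param codons character vector of 3-letter DNA codons (U is normalized to
#'   T). A trailing stop codon is stripped; internal stop codons are an error.
#' @param name sequence label.
#' @return object of class `codon_sequence` (a character vector with a `name`
#'   attribute).
#' @export
codon_sequence <- function(codons, name = "seq") {
  codons <- toupper(chartr("Uu", "Tt", as.character(codons)))
  if (length(codons) >= 1 && codons[length(codons)] %in% STOP_CODONS) {
    codons <- codons[-length(codons)]
  }
  if (length(codons) < 1) stop("sequence must contain at least one sense codon")
  bad <- !grepl("^[ACGT]{3}$", codons)
  if (any(bad)) {
    stop("invalid codon(s) at position(s) ",
         paste(head(which(bad), 5), collapse = ", "))
  }
  internal_stop <- codons %in% STOP_CODONS
  if (any(internal_stop)) {
    stop("internal stop codon at position ",
         paste(which(internal_stop), collapse = ", "))
  }
  structure(codons, name = name, class = "codon_sequence")
}

#' @export
print.codon_sequence <- function(x, ...) {
  cat("codon_sequence '", attr(x, "name"), "': ", length(x), " codons\n",
      sep = "")
  invisible(x)
}

#' Read a coding sequence from a single-record FASTA file
#'
#' @param path FASTA file with exactly one record whose length is divisible by
#'   3. A trailing stop codon (TAA/TAG/TGA) is removed; internal stop codons
#'   raise a validation error. RNA input (U) is normalized to DNA (T).
#' @return a [codon_sequence()].
#' @export
read_fasta_cds <- function(path) {
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) != 1) {
    stop("expected exactly one FASTA record, found ", length(recs))
  }
  s <- toupper(chartr("Uu", "Tt", as.character(recs[[1]])))
  if (nchar(s) %% 3 != 0) {
    stop("sequence length ", nchar(s), " is not divisible by 3")
  }
  codons <- substring(s, seq(1, nchar(s), by = 3), seq(3, nchar(s), by = 3))
  codon_sequence(codons, name = names(recs)[1])
}

#' Write a codon sequence to FASTA
#'
#' @param seq a [codon_sequence()].
#' @param path output file.
#' @export
write_fasta_cds <- function(seq, path) {
  x <- Biostrings::DNAStringSet(paste(seq, collapse = ""))
  names(x) <- attr(seq, "name")
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Bundled codon-to-tRNA-species assignment
#'
#' One-to-one map of each of the 61 sense codons to the single tRNA species
#' that serves it in this model. Wobble reading is collapsed onto the major
#' isoacceptor, matching the bundled abundance table's species naming.
#'
#' @param path optional TSV (columns `codon`, `species`) overriding the
#'   bundled map.
#' @return named character vector, codon -> species label.
#' @export
codon_trna_map <- function(path = NULL) {
  if (is.null(path)) path <- extdata_path("codon_trna_map.tsv")
  tab <- read.delim(path)
  map <- setNames(as.character(tab$species), toupper(tab$codon))
  if (length(map) == 0) stop("empty codon map")
  sense <- setdiff(all_codons(), STOP_CODONS)
  missing <- setdiff(sense, names(map))
  if (length(missing)) {
    stop("codon map is missing sense codon(s): ",
         paste(head(missing, 5), collapse = ", "))
  }
  map
}

all_codons <- function() {
  b <- c("T", "C", "A", "G")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

#' Map a codon sequence to its per-position tRNA species
#'
#' @param seq a [codon_sequence()].
#' @param map codon -> species map, default the bundled one.
#' @return character vector of species labels, one per codon.
#' @export
map_codons <- function(seq, map = codon_trna_map()) {
  if (length(map) == 0) stop("empty codon map")
  out <- unname(map[as.character(seq)])
  if (anyNA(out)) {
    i <- which(is.na(out))[1]
    stop("codon ", seq[i], " at position ", i, " has no tRNA assignment")
  }
  out
}

#' Generate a synthetic coding sequence with tunable adaptation to the tRNA pool
#'
#' Codons are drawn independently from a mixture distribution: with
#' probability `adaptation` a codon is drawn with probability proportional to
#' the abundance of its cognate tRNA species (divided evenly among the codons
#' served by that species, so the species-level demand matches the pool), and
#' otherwise uniformly over the 61 sense codons. `adaptation = 1` emulates a
#' codon-optimized native gene; `adaptation = 0` a non-adapted heterologous
#' gene such as GFP.
#'
#' @param length number of codons (>= 1).
#' @param adaptation mixture weight in `[0, 1]`.
#' @param trna named abundance vector (default: bundled in vivo table).
#' @param map codon -> species map.
#' @param seed integer seed; the result is deterministic given the seed.
#' @param name sequence label.
#' @return a [codon_sequence()].
#' @export
synth_codon_sequence <- function(length, adaptation, trna = NULL,
                                 map = codon_trna_map(), seed = 1,
                                 name = sprintf("synthetic_a%.2f", adaptation)) {
  stopifnot(length >= 1, adaptation >= 0, adaptation <= 1)
  if (is.null(trna)) trna <- load_default_tables()$trna
  w <- codon_weights(adaptation, trna, map)
  codons <- with_seed(seed, sample(names(w), length, replace = TRUE, prob = w))
  codon_sequence(codons, name = name)
}

#' Per-codon sampling weights used by [synth_codon_sequence()]
#'
#' @inheritParams synth_codon_sequence
#' @return named numeric vector over sense codons, summing to 1.
#' @export
codon_weights <- function(adaptation, trna, map = codon_trna_map()) {
  sp <- unname(map)
  missing <- setdiff(sp, names(trna))
  if (length(missing)) {
    stop("map targets species absent from the abundance table: ",
         paste(missing, collapse = ", "))
  }
  n_per_species <- table(sp)
  w_adapted <- trna[sp] / as.numeric(n_per_species[sp])
  w_adapted <- w_adapted / sum(w_adapted)
  w_uniform <- rep(1 / length(map), length(map))
  w <- adaptation * w_adapted + (1 - adaptation) * w_uniform
  setNames(as.numeric(w), names(map))
}

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic per-replicate seed derivation from a master seed.
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}
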