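# Domain model for coding sequences and protein variants: HGVS-p parsing,
# codon translation, and enumeration of the possible / SNV-reachable
# substitution universes.

# 20 standard amino acids, one-letter.
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA_THREE_TO_ONE <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V", Ter = "*"
)

translate_codons <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

#' Construct a validated coding sequence
#'
#' A `coding_sequence` is the source of truth for codon identities and
#' protein positions. The nucleotide string must have length divisible by
#' three, begin with ATG, and translate without internal stop codons; a
#' terminal stop codon, if present, is excluded from protein positions.
#'
#' @param nucleotides Character scalar over A/C/G/T (U is normalized to T,
#'   case-insensitive).
#' @param name Identifier for the sequence.
#' @return An object of class `coding_sequence` with elements `name`,
#'   `nucleotides`, `codons` (character vector of 3-mers), `protein`
#'   (one-letter amino acids, terminal stop excluded), and `protein_length`.
#' @examples
#' cds <- coding_sequence("ATGAAATGGTAA", "toy")
#' cds$protein          # "M" "K" "W"
#' cds$protein_length   # 3
#' @export
coding_sequence <- function(nucleotides, name = "cds") {
  stopifnot(is.character(nucleotides), length(nucleotides) == 1L)
  nt <- toupper(gsub("[ \t\r\n]", "", nucleotides))
  nt <- gsub("U", "T", nt, fixed = TRUE)
  bad <- regmatches(nt, regexpr("[^ACGT]", nt))
  if (length(bad) > 0) {
    stop("coding sequence contains non-ACGT character: '", bad, "'")
  }
  if (nchar(nt) %% 3L != 0L) {
    stop("coding sequence length (", nchar(nt), ") is not divisible by 3")
  }
  if (nchar(nt) < 6L) stop("coding sequence must contain at least 2 codons")
  codons <- substring(nt, seq(1L, nchar(nt) - 2L, by = 3L),
                      seq(3L, nchar(nt), by = 3L))
  if (codons[1] != "ATG") stop("coding sequence must begin with ATG")
  aa <- translate_codons(codons)
  n <- length(aa)
  has_terminal_stop <- aa[n] == "*"
  prot <- if (has_terminal_stop) aa[-n] else aa
  if (any(prot == "*")) {
    stop("coding sequence contains an internal stop codon at codon ",
         which(prot == "*")[1])
  }
  structure(
    list(name = name, nucleotides = nt, codons = codons, protein = prot,
         protein_length = length(prot), has_terminal_stop = has_terminal_stop),
    class = "coding_sequence"
  )
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat("coding_sequence '", x$name, "': ", nchar(x$nucleotides), " nt, ",
      x$protein_length, " aa",
      if (x$has_terminal_stop) " (+ terminal stop)", "\n", sep = "")
  invisible(x)
}

#' Read a coding sequence from a FASTA file
#'
#' Reads a single-record FASTA file, upper-cases the sequence, normalizes
#' U to T, and validates it as a [coding_sequence()].
#'
#' @param path Path to a FASTA file containing exactly one record.
#' @return A `coding_sequence`.
#' @export
read_cds <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) != 1L) {
    stop("expected exactly 1 FASTA record in '", path, "', found ", length(set))
  }
  coding_sequence(as.character(set[[1]]), name = names(set)[1])
}

variant_class <- function(wt_aa, alt_aa) {
  ifelse(alt_aa == "*", "nonsense",
         ifelse(wt_aa == alt_aa, "synonymous", "missense"))
}

#' Format protein variants as HGVS-p strings
#'
#' Canonical one-letter form, stop rendered `*`.
#'
#' @param position 1-based residue positions.
#' @param wt_aa,alt_aa One-letter amino acids (`*` for stop).
#' @return Character vector like `"p.K78I"`.
#' @export
format_hgvs_pro <- function(position, wt_aa, alt_aa) {
  paste0("p.", wt_aa, position, alt_aa)
}

decode_aa_token <- function(token, text) {
  out <- character(length(token))
  one <- nchar(token) == 1L
  out[one] <- toupper(token[one])
  three <- !one
  if (any(three)) {
    key <- paste0(toupper(substr(token[three], 1, 1)),
                  tolower(substr(token[three], 2, 3)))
    out[three] <- AA_THREE_TO_ONE[key]
  }
  bad <- is.na(out) | !(out %in% c(AA_ALPHABET, "*"))
  if (any(bad)) {
    stop("unknown amino-acid code '", token[bad][1], "' in '", text[bad][1], "'")
  }
  out
}

#' Parse HGVS-p substitution strings
#'
#' Accepts one- and three-letter amino-acid codes (`p.K78I`, `p.Lys78Ile`),
#' stop as `*` or `Ter`, and the synonymous shorthand `p.K78=`. Output is
#' canonicalized to one-letter form with stop rendered `*`.
#'
#' @param text Character vector of HGVS-p substitution strings.
#' @return A data.frame with columns `hgvs_pro` (canonical form), `position`,
#'   `wt_aa`, `alt_aa`, and `vclass` (missense/synonymous/nonsense).
#' @examples
#' parse_hgvs_pro(c("p.K78I", "p.Leu286Ter", "p.K78K"))
#' @export
parse_hgvs_pro <- function(text) {
  stopifnot(is.character(text), length(text) >= 1L)
  pat <- "^p\\.\\(?([A-Za-z]{1}|[A-Za-z]{3})([0-9]+)((?:[A-Za-z]{1}|[A-Za-z]{3}|\\*|=))\\)?$"
  m <- regmatches(text, regexec(pat, text))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("malformed HGVS-p string: '", text[bad][1], "'")
  }
  wt_tok <- vapply(m, `[[`, "", 2L)
  pos <- as.integer(vapply(m, `[[`, "", 3L))
  alt_tok <- vapply(m, `[[`, "", 4L)
  if (any(pos < 1L)) {
    stop("invalid position '", pos[pos < 1L][1], "' in '",
         text[pos < 1L][1], "'")
  }
  wt <- decode_aa_token(wt_tok, text)
  if (any(wt == "*")) stop("wild-type residue may not be a stop: '",
                           text[wt == "*"][1], "'")
  alt <- character(length(text))
  alt[alt_tok == "="] <- wt[alt_tok == "="]
  alt[alt_tok == "*"] <- "*"
  rest <- !(alt_tok %in% c("=", "*"))
  if (any(rest)) alt[rest] <- decode_aa_token(alt_tok[rest], text[rest])
  data.frame(
    hgvs_pro = format_hgvs_pro(pos, wt, alt),
    position = pos, wt_aa = wt, alt_aa = alt,
    vclass = variant_class(wt, alt),
    stringsAsFactors = FALSE
  )
}

#' Translate codon variants to protein variants
#'
#' Maps codon-level changes to amino-acid changes through the standard
#' genetic code, verifying that the stated wild-type codon matches the CDS.
#'
#' @param cds A [coding_sequence()].
#' @param codon_position 1-based codon indices (vectorized).
#' @param wt_codon,alt_codon Codon 3-mers; `alt_codon` must differ from
#'   `wt_codon`.
#' @return A data.frame with `position`, `wt_aa`, `alt_aa`, `vclass`,
#'   `hgvs_pro` plus the input codon columns.
#' @export
translate_codon_variant <- function(cds, codon_position, wt_codon, alt_codon) {
  stopifnot(inherits(cds, "coding_sequence"))
  wt_codon <- toupper(wt_codon)
  alt_codon <- toupper(alt_codon)
  if (any(codon_position < 1L | codon_position > cds$protein_length)) {
    stop("codon_position outside protein positions 1..", cds$protein_length)
  }
  mismatch <- cds$codons[codon_position] != wt_codon
  if (any(mismatch)) {
    i <- which(mismatch)[1]
    stop("wt_codon '", wt_codon[i], "' does not match CDS codon '",
         cds$codons[codon_position[i]], "' at codon ", codon_position[i])
  }
  if (any(wt_codon == alt_codon)) stop("alt_codon must differ from wt_codon")
  wt_aa <- translate_codons(wt_codon)
  alt_aa <- translate_codons(alt_codon)
  data.frame(
    position = as.integer(codon_position),
    wt_codon = wt_codon, alt_codon = alt_codon,
    wt_aa = wt_aa, alt_aa = alt_aa,
    vclass = variant_class(wt_aa, alt_aa),
    hgvs_pro = format_hgvs_pro(codon_position, wt_aa, alt_aa),
    stringsAsFactors = FALSE
  )
}

#' Enumerate all possible amino-acid substitutions
#'
#' Every (position, alternate amino acid) pair with the alternate drawn from
#' the 19 non-wild-type standard amino acids. Position 1 (the initiator
#' methionine) is excluded from the universe, so the count is exactly
#' `19 * (L - 1)` for a protein of length L; for the 433-residue kinase this
#' gives the 8,208-substitution universe used for coverage accounting.
#'
#' @param protein A `coding_sequence`, or a character vector of one-letter
#'   amino acids, or a single amino-acid string.
#' @return A data.frame with `position`, `wt_aa`, `alt_aa`, `hgvs_pro`
#'   (all missense; stops are not part of the substitution universe).
#' @examples
#' nrow(enumerate_possible_substitutions(strrep("A", 432))) # within a string
#' @export
enumerate_possible_substitutions <- function(protein) {
  if (inherits(protein, "coding_sequence")) {
    prot <- protein$protein
  } else if (is.character(protein) && length(protein) == 1L && nchar(protein) > 1L) {
    prot <- strsplit(protein, "")[[1]]
  } else {
    prot <- protein
  }
  stopifnot(is.character(prot), all(prot %in% AA_ALPHABET))
  L <- length(prot)
  if (L < 2L) stop("protein must have at least 2 residues")
  pos <- rep(2:L, each = 19L)
  wt <- prot[pos]
  alt <- unlist(lapply(2:L, function(i) setdiff(AA_ALPHABET, prot[i])),
                use.names = FALSE)
  data.frame(
    position = pos, wt_aa = wt, alt_aa = alt,
    hgvs_pro = format_hgvs_pro(pos, wt, alt),
    stringsAsFactors = FALSE
  )
}

#' Substitutions reachable by a single nucleotide change
#'
#' For every codon of the CDS, all nine single-nucleotide mutants are
#' translated. Distinct missense (position, alternate) pairs are returned,
#' with synonymous and nonsense reachability reported separately. Variants
#' at position 1 are excluded from the missense set, matching the possible-
#' substitution universe.
#'
#' @param cds A [coding_sequence()].
#' @return A list with data.frames `missense`, `synonymous`, `nonsense`
#'   (each distinct on position/alt), and a `counts` named vector.
#' @examples
#' cds <- coding_sequence("ATGAAATGGTAA", "toy")
#' snv_reachable_set(cds)$counts
#' @export
snv_reachable_set <- function(cds) {
  stopifnot(inherits(cds, "coding_sequence"))
  bases <- c("A", "C", "G", "T")
  L <- cds$protein_length
  wt_codons <- cds$codons[seq_len(L)]
  recs <- vector("list", L)
  for (i in seq_len(L)) {
    wt <- wt_codons[i]
    wt_split <- strsplit(wt, "")[[1]]
    muts <- character(9L)
    k <- 0L
    for (b in 1:3) {
      for (nb in setdiff(bases, wt_split[b])) {
        mt <- wt_split
        mt[b] <- nb
        k <- k + 1L
        muts[k] <- paste(mt, collapse = "")
      }
    }
    alt_aa <- translate_codons(muts)
    wt_aa <- translate_codons(wt)
    recs[[i]] <- data.frame(
      position = i, wt_aa = wt_aa, alt_aa = alt_aa,
      vclass = variant_class(wt_aa, alt_aa),
      stringsAsFactors = FALSE
    )
  }
  all <- do.call(rbind, recs)
  distinct <- function(df) {
    df <- df[!duplicated(df[c("position", "alt_aa")]), , drop = FALSE]
    df$hgvs_pro <- if (nrow(df) > 0) {
      format_hgvs_pro(df$position, df$wt_aa, df$alt_aa)
    } else character(0)
    rownames(df) <- NULL
    df
  }
  mis <- distinct(all[all$vclass == "missense" & all$position >= 2L, ])
  syn <- distinct(all[all$vclass == "synonymous", ])
  non <- distinct(all[all$vclass == "nonsense", ])
  list(
    missense = mis, synonymous = syn, nonsense = non,
    counts = c(missense = nrow(mis), synonymous = nrow(syn),
               nonsense = nrow(non))
  )
}

#' Write a variant set as MaveDB-style CSV
#'
#' @param variants A data.frame containing at least an `hgvs_pro` column.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_variants_csv <- function(variants, path) {
  stopifnot("hgvs_pro" %in% names(variants))
  utils::write.csv(variants, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
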