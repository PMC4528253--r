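#' Controlled vocabulary for modification types
#'
#' Source databases label the same chemistry in many ways ("Phospho",
#' "phosphorylation (S)", "Ubiquitylation", ...). `normalize_mod_type()`
#' folds labels case-insensitively onto a small controlled vocabulary;
#' anything unrecognised passes through as `other:<label>` so no record is
#' ever dropped for vocabulary reasons.
#'
#' @param x character vector of raw modification labels.
#' @return character vector of normalized labels.
#' @examples
#' normalize_mod_type(c("Phospho", "UBIQUITINATION", "sumoylation"))
#' @export
normalize_mod_type <- function(x) {
  stopifnot(is.character(x))
  key <- tolower(trimws(x))
  # strip residue qualifiers like "phosphorylation (S)" or "phospho-ser"
  key <- sub("[[:space:]]*\\([a-z/, ]+\\)$", "", key)
  hit <- MOD_SYNONYMS[key]
  out <- ifelse(is.na(hit), ifelse(grepl("^other:", key), key,
                                   paste0("other:", key)), hit)
  out[!nzchar(trimws(x))] <- NA_character_
  unname(out)
}

MOD_VOCAB <- c("phosphorylation", "ubiquitination", "acetylation",
               "methylation", "palmitoylation", "myristoylation",
               "prenylation", "s-nitrosylation")

MOD_SYNONYMS <- local({
  syn <- c(
    phosphorylation  = "phosphorylation",
    phospho          = "phosphorylation",
    phosphorylated   = "phosphorylation",
    ubiquitination   = "ubiquitination",
    ubiquitylation   = "ubiquitination",
    ubiquitin        = "ubiquitination",
    acetylation      = "acetylation",
    acetyl           = "acetylation",
    methylation      = "methylation",
    methyl           = "methylation",
    trimethylation   = "methylation",
    dimethylation    = "methylation",
    palmitoylation   = "palmitoylation",
    palmitoyl        = "palmitoylation",
    myristoylation   = "myristoylation",
    myristoyl        = "myristoylation",
    prenylation      = "prenylation",
    geranylgeranylation = "prenylation",
    farnesylation    = "prenylation",
    `s-nitrosylation` = "s-nitrosylation",
    nitrosylation    = "s-nitrosylation"
  )
  syn
})

# Residues chemically modifiable by each PTM type, used for PRC
# (e.g. S/T/Y for phosphorylation, K for ubiquitination).
MODIFIABLE_RESIDUES <- list(
  phosphorylation   = c("S", "T", "Y"),
  ubiquitination    = "K",
  acetylation       = "K",
  methylation       = c("K", "R"),
  palmitoylation    = "C",
  `s-nitrosylation` = "C",
  prenylation       = "C",
  myristoylation    = "G"
)

#' Residues modifiable by a set of PTM types
#'
#' Union of the modifiable-residue sets for the given types. For
#' `other:<label>` types, which have no table entry, the residues actually
#' observed modified (`observed` argument) stand in.
#'
#' @param mod_types character vector of normalized mod types.
#' @param observed residues observed modified (used for `other:` types).
#' @return character vector of one-letter codes.
#' @export
modifiable_residues <- function(mod_types, observed = character()) {
  known <- unlist(MODIFIABLE_RESIDUES[intersect(mod_types, names(MODIFIABLE_RESIDUES))])
  extra <- if (any(grepl("^other:", mod_types))) observed else character()
  sort(unique(c(known, extra)))
}
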