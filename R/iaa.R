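#' Indispensable amino acid scoring groups
#'
#' The nine indispensable amino acid (IAA) groups used for protein-quality
#' scoring, in fixed order. The sulphur amino acids (SAA = methionine +
#' cysteine) and the aromatic amino acids (AAA = phenylalanine + tyrosine)
#' are stored pre-combined because adult scoring patterns define their
#' requirements jointly.
#'
#' @return Character vector of length 9:
#'   `His, Ile, Leu, Lys, SAA, AAA, Thr, Trp, Val`.
#' @export
#' @examples
#' iaa_names()
iaa_names <- function() {
  c("His", "Ile", "Leu", "Lys", "SAA", "AAA", "Thr", "Trp", "Val")
}

# lower-case column names used for per-100 g IAA content in food tables
iaa_cols <- function() tolower(iaa_names())

#' Adult amino acid scoring pattern
#'
#' The WHO/FAO/UNU (2007) adult amino acid scoring pattern, in mg of each
#' indispensable amino acid per g of protein. This is the packaged default
#' reference used to score meal protein quality; an alternative pattern can
#' be supplied via [load_reference_pattern()].
#'
#' @return A `reference_pattern`: named numeric vector over [iaa_names()]
#'   (mg IAA per g protein) with a `source_label` attribute.
#' @export
#' @examples
#' who_reference_pattern()
who_reference_pattern <- function() {
  new_reference_pattern(
    c(His = 15, Ile = 30, Leu = 59, Lys = 45, SAA = 22,
      AAA = 38, Thr = 23, Trp = 6, Val = 39),
    source_label = "WHO/FAO/UNU 2007 adult scoring pattern"
  )
}

new_reference_pattern <- function(values, source_label = "unspecified") {
  values <- values[iaa_names()]
  validate_reference_pattern(values)
  structure(unlist(values), source_label = source_label,
            class = c("reference_pattern", "numeric"))
}

validate_reference_pattern <- function(values) {
  missing <- setdiff(iaa_names(), names(values)[!is.na(values)])
  if (length(missing) > 0) {
    abort(paste0("reference pattern is missing IAA key(s): ",
                 paste(missing, collapse = ", ")),
          class = "dietshift_config_error")
  }
  if (any(unlist(values) <= 0)) {
    bad <- names(values)[unlist(values) <= 0]
    abort(paste0("reference pattern values must be strictly positive; ",
                 "offending key(s): ", paste(bad, collapse = ", ")),
          class = "dietshift_validation_error")
  }
  invisible(values)
}

#' Load a reference amino acid pattern from a YAML/JSON config file
#'
#' The file must provide one strictly positive value (mg IAA per g protein)
#' for each of the nine scoring groups in [iaa_names()]. An optional
#' `source_label` entry is carried along as provenance.
#'
#' @param path Path to a YAML (or JSON, which YAML subsumes) file mapping
#'   IAA name to mg per g protein.
#' @return A `reference_pattern` (see [who_reference_pattern()]).
#' @export
load_reference_pattern <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("reference pattern file not found: ", path),
          class = "dietshift_config_error")
  }
  raw <- yaml::read_yaml(path)
  label <- raw$source_label %||% basename(path)
  raw$source_label <- NULL
  vals <- vapply(raw, as.numeric, numeric(1))
  new_reference_pattern(vals, source_label = label)
}

#' @export
print.reference_pattern <- function(x, ...) {
  cat("<reference_pattern> ", attr(x, "source_label"), "\n", sep = "")
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}
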