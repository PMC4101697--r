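#' Default assay-type registry
#'
#' Every registry starts with the stock set of supported assay types:
#' five sequencing assays (mRNA-seq, ChIP-seq, DNase-seq, Methyl-seq,
#' miRNA-seq) plus Proteomics and Metabolomics. The set is user-extensible
#' with [add_assay_type()]. Tag matching everywhere in the package is
#' case-insensitive and whitespace-trimmed, and tags are stored canonically,
#' so "mrna-seq" and "mRNA-seq " resolve to the same assay while remaining
#' distinct from, say, "miRNA-seq".
#'
#' @return A tibble with columns `tag` and `category`
#'   (sequencing / proteomics / metabolomics).
#' @export
#' @examples
#' default_assay_types()
default_assay_types <- function() {
  tibble::tibble(
    tag = c("mRNA-seq", "ChIP-seq", "DNase-seq", "Methyl-seq", "miRNA-seq",
            "Proteomics", "Metabolomics"),
    category = c(rep("sequencing", 5), "proteomics", "metabolomics")
  )
}

ASSAY_CATEGORIES <- c("sequencing", "proteomics", "metabolomics")

norm_tag <- function(tag) tolower(trimws(tag))

#' Assay types registered in a registry
#'
#' @param registry An [ems_registry()].
#' @return Tibble with columns `tag` and `category`, ordered by tag.
#' @export
assay_types <- function(registry) {
  check_registry(registry)
  dplyr::arrange(registry$assay_types, .data$tag)
}

#' Register an additional assay type
#'
#' @param registry An [ems_registry()].
#' @param tag New assay tag (e.g. `"ATAC-seq"`); must not collide
#'   case-insensitively with an existing tag.
#' @param category One of `"sequencing"`, `"proteomics"`, `"metabolomics"`.
#' @return The tag, invisibly.
#' @export
add_assay_type <- function(registry, tag, category) {
  check_registry(registry)
  if (!is_nonempty_string(tag)) {
    abort_validation("assay tag must be a non-empty string")
  }
  category <- match.arg(category, ASSAY_CATEGORIES)
  tag <- trimws(tag)
  if (norm_tag(tag) %in% norm_tag(registry$assay_types$tag)) {
    abort_validation(sprintf("assay tag '%s' is already registered", tag))
  }
  registry$assay_types <- dplyr::bind_rows(
    registry$assay_types,
    tibble::tibble(tag = tag, category = category)
  )
  invisible(tag)
}

#' Resolve an assay tag to its canonical registered form
#'
#' @param registry An [ems_registry()].
#' @param tag Assay tag in any letter case, surrounding whitespace ignored.
#' @return The canonical tag string.
#' @export
canonical_assay_tag <- function(registry, tag) {
  check_registry(registry)
  if (!is_nonempty_string(tag)) {
    abort_validation("assay tag must be a non-empty string")
  }
  hit <- match(norm_tag(tag), norm_tag(registry$assay_types$tag))
  if (is.na(hit)) {
    abort_validation(sprintf(
      "unregistered assay type '%s'; registered tags: %s",
      trimws(tag), paste(sort(registry$assay_types$tag), collapse = ", ")
    ))
  }
  registry$assay_types$tag[[hit]]
}

is_nonempty_string <- function(x) {
  is.character(x) && length(x) == 1 && !is.na(x) && nzchar(trimws(x))
}
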