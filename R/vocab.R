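#' ATC vocabulary for the anti-hyperlipidemic study drugs
#'
#' Builds the controlled vocabulary used throughout the pipeline: the six
#' study monotherapy classes (five statin compounds plus fibrates), the
#' fixed-dose combination prefix, the co-medication proxy groups used as
#' baseline drug-treated comorbidity flags, and the cohort exclusion lists.
#'
#' Study classes are matched by ATC prefix: simvastatin `C10AA01`,
#' pravastatin `C10AA03`, fluvastatin `C10AA04`, atorvastatin `C10AA05`,
#' rosuvastatin `C10AA07`, and fibrates `C10AB` (any compound).
#'
#' The co-medication map ships explicit defaults (diabetes = A10,
#' rheumatoid arthritis = M01A/L04A, asthma/COPD = R03, antiepileptics = N03,
#' antiparkinson = N04, psycholeptics = N05, psychoanaleptics = N06,
#' addictive-disorder drugs = N07B, antineoplastics = L01). The named drug
#' groups are standard; the exact prefix lists are configuration, not a
#' registry standard, and can be overridden per run.
#'
#' The cardiac exclusion list (`exclusion_map$cardiac`, default C01 cardiac
#' therapy plus B01 antithrombotics) is a reconstruction of the usual
#' acute/chronic cardiac drug proxy used with dispensing-only databases;
#' override it when a protocol-specific list is available.
#'
#' @param study_classes named character vector of ATC prefixes, one per study
#'   class; names are the class labels used everywhere downstream.
#' @param fixed_combination ATC prefix of fixed-dose lipid-lowering
#'   combinations (counts as a switch/add-on target, and as an exclusion in
#'   the first year).
#' @param comedication_map named list of character vectors of ATC prefixes,
#'   one entry per baseline comorbidity flag.
#' @param exclusion_map named list with elements `antihypertensive`,
#'   `fixed_combination` and `cardiac`, each a character vector of ATC
#'   prefixes.
#' @return an object of class `atc_vocabulary` (a list with the four
#'   components above).
#' @export
atc_vocabulary <- function(study_classes = c(
                             simvastatin  = "C10AA01",
                             pravastatin  = "C10AA03",
                             fluvastatin  = "C10AA04",
                             atorvastatin = "C10AA05",
                             rosuvastatin = "C10AA07",
                             fibrates     = "C10AB"
                           ),
                           fixed_combination = "C10BX",
                           comedication_map = list(
                             diabetes            = "A10",
                             ra                  = c("M01A", "L04A"),
                             asthma_copd         = "R03",
                             antiepileptics      = "N03",
                             antiparkinson       = "N04",
                             psycholeptics       = "N05",
                             psychoanaleptics    = "N06",
                             addictive_disorders = "N07B",
                             antineoplastics     = "L01"
                           ),
                           exclusion_map = list(
                             antihypertensive  = c("C02", "C03", "C07", "C08", "C09"),
                             fixed_combination = "C10BX",
                             cardiac           = c("C01", "B01")
                           )) {
  stopifnot(is.character(study_classes), length(study_classes) >= 1,
            !is.null(names(study_classes)), all(nzchar(names(study_classes))))
  # prefixes of study classes must not nest inside one another
  for (i in seq_along(study_classes)) {
    for (j in seq_along(study_classes)) {
      if (i != j && startsWith(study_classes[[i]], study_classes[[j]])) {
        stop("study class prefixes overlap: ", study_classes[[j]],
             " is a prefix of ", study_classes[[i]])
      }
    }
  }
  structure(
    list(study_classes = study_classes,
         fixed_combination = fixed_combination,
         comedication_map = comedication_map,
         exclusion_map = exclusion_map),
    class = "atc_vocabulary"
  )
}

#' Map an ATC code to its study class
#'
#' Longest-prefix match of `atc` against the vocabulary's study classes.
#' Vectorised; codes matching no study prefix return `NA`.
#'
#' @param atc character vector of ATC codes.
#' @param vocab an [atc_vocabulary()].
#' @return character vector of class labels (or `NA` where no study drug).
#' @examples
#' v <- atc_vocabulary()
#' classify_atc(c("C10AA01", "C10AB05", "A10BA02"), v)
#' @export
classify_atc <- function(atc, vocab = atc_vocabulary()) {
  stopifnot(inherits(vocab, "atc_vocabulary"))
  prefixes <- vocab$study_classes
  # order by decreasing prefix length => first hit is the longest match
  ord <- order(nchar(prefixes), decreasing = TRUE)
  prefixes <- prefixes[ord]
  out <- rep(NA_character_, length(atc))
  for (k in seq_along(prefixes)) {
    hit <- is.na(out) & startsWith(atc, prefixes[[k]])
    out[hit] <- names(prefixes)[[k]]
  }
  out
}

#' @rdname classify_atc
#' @details `is_fixed_combination()` flags codes under the fixed-dose
#'   combination prefix; `matches_any_prefix()` is the generic prefix test
#'   used for co-medication and exclusion lists.
#' @export
is_fixed_combination <- function(atc, vocab = atc_vocabulary()) {
  startsWith(atc, vocab$fixed_combination)
}

#' @rdname classify_atc
#' @param prefixes character vector of ATC prefixes.
#' @export
matches_any_prefix <- function(atc, prefixes) {
  out <- rep(FALSE, length(atc))
  for (p in prefixes) out <- out | startsWith(atc, p)
  out
}
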