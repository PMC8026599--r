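#' Analyte class composition of the targeted panel
#'
#' The targeted assay quantifies up to 188 endogenous metabolites in nine
#' classes: free carnitine (C0), 39 acylcarnitines, the hexose sum (H1),
#' 21 amino acids, 21 biogenic amines, and 105 lipids split into
#' 14 lysophosphatidylcholines, 38 diacyl- and 38 acyl-alkyl-
#' phosphatidylcholines, and 15 sphingomyelins.
#'
#' @return A data.frame with columns `class` and `expected_count`.
#' @export
panel_class_counts <- function() {
  data.frame(
    class = c("acylcarnitine_free", "acylcarnitine", "hexoses", "amino_acid",
              "biogenic_amine", "lysoPC", "PC_aa", "PC_ae", "sphingomyelin"),
    expected_count = c(1L, 39L, 1L, 21L, 21L, 14L, 38L, 38L, 15L),
    stringsAsFactors = FALSE
  )
}

# Lipid classes of the panel (sum to 105 analytes).
lipid_classes <- c("lysoPC", "PC_aa", "PC_ae", "sphingomyelin")

#' Build the default analyte panel registry
#'
#' Returns the default 188-analyte registry. Amino acids and biogenic amines
#' carry their conventional short names (Ala ... Val, DOPA, Met_SO, ...);
#' the lipid and acylcarnitine entries use synthesized per-class identifiers
#' because the individual species names are kit-specific. Real panel exports
#' can be ingested against a user-supplied registry built with
#' [panel_registry()].
#'
#' @return An object of class `panel_registry`: a data.frame with columns
#'   `analyte_id` and `class`, one row per analyte.
#' @examples
#' reg <- p180_registry()
#' nrow(reg)            # 188
#' table(reg$class)
#' @export
p180_registry <- function() {
  amino_acids <- c("Ala", "Arg", "Asn", "Asp", "Cit", "Gln", "Glu", "Gly",
                   "His", "Ile", "Leu", "Lys", "Met", "Orn", "Phe", "Pro",
                   "Ser", "Thr", "Trp", "Tyr", "Val")
  biogenic_amines <- c("Ac_Orn", "ADMA", "alpha_AAA", "Carnosine",
                       "Creatinine", "DOPA", "Dopamine", "Histamine",
                       "Kynurenine", "Met_SO", "Nitro_Tyr", "PEA",
                       "Putrescine", "Sarcosine", "SDMA", "Serotonin",
                       "Spermidine", "Spermine", "t4_OH_Pro", "Taurine",
                       "total_DMA")
  ids <- list(
    acylcarnitine_free = "C0",
    acylcarnitine      = sprintf("AC%02d", 1:39),
    hexoses            = "H1",
    amino_acid         = amino_acids,
    biogenic_amine     = biogenic_amines,
    lysoPC             = sprintf("lysoPC_C%02d", 1:14),
    PC_aa              = sprintf("PC_aa_C%02d", 1:38),
    PC_ae              = sprintf("PC_ae_C%02d", 1:38),
    sphingomyelin      = sprintf("SM_C%02d", 1:15)
  )
  panel_registry(data.frame(
    analyte_id = unlist(ids, use.names = FALSE),
    class = rep(names(ids), lengths(ids)),
    stringsAsFactors = FALSE
  ))
}

#' Construct a panel registry from an analyte table
#'
#' @param analytes data.frame with columns `analyte_id` and `class`.
#' @return A `panel_registry` object.
#' @export
panel_registry <- function(analytes) {
  if (!is.data.frame(analytes) || !all(c("analyte_id", "class") %in% names(analytes)))
    stopf("registry requires a data.frame with columns 'analyte_id' and 'class'")
  if (anyDuplicated(analytes$analyte_id))
    stopf("duplicate analyte ids in registry: %s",
          paste(unique(analytes$analyte_id[duplicated(analytes$analyte_id)]), collapse = ", "))
  analytes <- analytes[, c("analyte_id", "class")]
  analytes$analyte_id <- as.character(analytes$analyte_id)
  analytes$class <- as.character(analytes$class)
  rownames(analytes) <- NULL
  structure(analytes, class = c("panel_registry", "data.frame"))
}

#' Look up an analyte in a registry
#'
#' @param registry a `panel_registry`.
#' @param analyte_id analyte identifier(s).
#' @return The registry rows for the requested analytes.
#' @export
registry_lookup <- function(registry, analyte_id) {
  idx <- match(analyte_id, registry$analyte_id)
  if (anyNA(idx))
    stopf("analyte(s) not in registry: %s",
          paste(analyte_id[is.na(idx)], collapse = ", "))
  registry[idx, , drop = FALSE]
}

#' @export
print.panel_registry <- function(x, ...) {
  cat(sprintf("Analyte panel registry: %d analytes, %d classes\n",
              nrow(x), length(unique(x$class))))
  print(table(class = x$class))
  invisible(x)
}
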