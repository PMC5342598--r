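#' @keywords internal
"_PACKAGE"

# Canonical assay identifiers for the qPCR panel. ACTB is the reference gene;
# the *_TOTAL assays measure all splice variants of a receptor together and
# are used only for positivity calling (variant percentages are computed from
# the variant-specific assays).
ASSAYS <- c(
  "NKP44_TOTAL", "NKP44_1", "NKP44_2", "NKP44_3",
  "NKP30_TOTAL", "NKP30_A", "NKP30_B", "NKP30_C",
  "NKP46", "ACTB"
)

RECEPTORS <- c("NKP44", "NKP30")

# Variant-specific assays per receptor, in reporting order.
RECEPTOR_VARIANTS <- list(
  NKP44 = c("NKP44_1", "NKP44_2", "NKP44_3"),
  NKP30 = c("NKP30_A", "NKP30_B", "NKP30_C")
)

RECEPTOR_TOTALS <- c(NKP44 = "NKP44_TOTAL", NKP30 = "NKP30_TOTAL")

#' qPCR assay metadata
#'
#' Returns the amplification-efficiency metadata for the assay panel, as
#' published for the primer sets. Efficiencies are close enough to 100% that
#' plain \eqn{2^{-\Delta Ct}} quantification is used throughout; this table is
#' carried as metadata only and no efficiency correction is applied.
#'
#' @return A data frame with columns `assay`, `efficiency_percent` and `role`
#'   (`"target"`, `"reference"` for the housekeeping gene, `"total_reference"`
#'   for the receptor-total assays used in positivity calls).
#' @export
#' @examples
#' assay_metadata()
assay_metadata <- function() {
  meta <- data.frame(
    assay = ASSAYS,
    efficiency_percent = c(98.6, 99.8, 102.5, 99.2,
                           100.205, 98.568, 98.387, 101.560,
                           104.432, 103.251),
    role = c("total_reference", "target", "target", "target",
             "total_reference", "target", "target", "target",
             "target", "reference"),
    stringsAsFactors = FALSE
  )
  stopifnot(all(meta$efficiency_percent > 50 & meta$efficiency_percent < 150))
  meta
}

# Normalise a user-supplied assay label to the canonical enum, accepting
# case-insensitive input and common punctuation variants (dashes/spaces for
# underscores, e.g. "NKp44-1", "nkp30a", "beta-actin").
normalize_assay <- function(x) {
  up <- toupper(trimws(x))
  up <- gsub("[ -]", "_", up)
  up[up %in% c("B_ACTIN", "BETA_ACTIN", "BACTIN", "B_ACT")] <- "ACTB"
  # allow NKP30A / NKP30_A style
  up <- sub("^(NKP30)([ABC])$", "\\1_\\2", up)
  up <- sub("^(NKP44)([123])$", "\\1_\\2", up)
  bad <- !(up %in% ASSAYS)
  if (any(bad)) {
    stop("unknown assay name(s): ", paste(unique(x[bad]), collapse = ", "),
         "; expected one of ", paste(ASSAYS, collapse = ", "), call. = FALSE)
  }
  up
}

# Short variant labels used in percentage tables.
variant_short_label <- function(assay) {
  c(NKP44_1 = "NKp44-1", NKP44_2 = "NKp44-2", NKP44_3 = "NKp44-3",
    NKP30_A = "NKp30a", NKP30_B = "NKp30b", NKP30_C = "NKp30c")[assay]
}
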