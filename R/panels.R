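#' Taxon panel configuration
#'
#' A `panel_config` records, per sample type, the genus panel retained after
#' filtering, the name used for *Lactobacillus* (the anchor of the
#' Lactobacillus-minus-other-taxa statistic), the chronic-endometritis (CE)
#' pathogen list, and the kitome exclusion list of recurrent reagent
#' contaminants.
#'
#' @param panel_taxa Named list of character vectors, one per sample type
#'   (typically `EF` and `EB`).
#' @param lactobacillus Genus name of the anchor taxon; must be present in
#'   every panel.
#' @param ce_pathogens Ordered genus list screened as CE-associated pathogens.
#' @param kitome_exclusions Genus list removed as reagent ("kitome")
#'   contaminants. The shipped default is a replaceable stand-in list of
#'   classic reagent genera; supply your own list to mirror a specific
#'   literature consensus.
#' @return A list of class `panel_config`.
#' @export
panel_config <- function(panel_taxa,
                         lactobacillus = "Lactobacillus",
                         ce_pathogens = default_ce_pathogens(),
                         kitome_exclusions = default_kitome_exclusions()) {
  if (!is.list(panel_taxa) || is.null(names(panel_taxa))) {
    abort("`panel_taxa` must be a named list of genus vectors.")
  }
  for (type in names(panel_taxa)) {
    if (!lactobacillus %in% panel_taxa[[type]]) {
      abort(sprintf(
        "Anchor genus '%s' missing from the %s panel; the Lactobacillus-difference statistic is undefined without it.",
        lactobacillus, type
      ))
    }
  }
  structure(
    list(
      panel_taxa = lapply(panel_taxa, as.character),
      lactobacillus = lactobacillus,
      ce_pathogens = as.character(ce_pathogens),
      kitome_exclusions = as.character(kitome_exclusions)
    ),
    class = "panel_config"
  )
}

#' @export
print.panel_config <- function(x, ...) {
  cat("<panel_config>\n")
  for (type in names(x$panel_taxa)) {
    cat(sprintf("  %s panel: %d genera\n", type, length(x$panel_taxa[[type]])))
  }
  cat(sprintf("  anchor: %s | CE pathogens: %d | kitome exclusions: %d\n",
              x$lactobacillus, length(x$ce_pathogens),
              length(x$kitome_exclusions)))
  invisible(x)
}

#' Default genus panels for endometrial fluid and biopsy
#'
#' The default panels are the published endometrial genus panels: 12 genera
#' shared between endometrial fluid (EF) and endometrial biopsy (EB), three
#' EF-only genera (*Streptomyces*, *Clostridium*, *Chryseobacterium*) and
#' seven EB-only genera, giving panels of 15 (EF) and 19 (EB).
#'
#' @return A [panel_config()].
#' @export
default_panel_config <- function() {
  shared <- c(
    "Lactobacillus", "Anaerococcus", "Atopobium", "Bifidobacterium",
    "Corynebacterium", "Gardnerella", "Haemophilus", "Microbacterium",
    "Prevotella", "Propionibacterium", "Staphylococcus", "Streptococcus"
  )
  ef_only <- c("Streptomyces", "Clostridium", "Chryseobacterium")
  eb_only <- c("Cupriavidus", "Escherichia", "Klebsiella", "Bacillus",
               "Finegoldia", "Micrococcus", "Tepidimonas")
  panel_config(list(EF = c(shared, ef_only), EB = c(shared, eb_only)))
}

#' @rdname default_panel_config
#' @export
default_ce_pathogens <- function() {
  c("Enterococcus", "Escherichia", "Klebsiella", "Streptococcus",
    "Staphylococcus", "Gardnerella", "Mycoplasma", "Ureaplasma",
    "Chlamydia", "Neisseria")
}

#' @rdname default_panel_config
#' @export
default_kitome_exclusions <- function() {
  path <- system.file("extdata", "kitome_default.txt", package = "endomicro")
  if (nzchar(path)) {
    readLines(path, warn = FALSE) |> trimws() |> Filter(f = nzchar, x = _)
  } else {
    # fallback when running from a source checkout
    c("Ralstonia", "Sphingomonas", "Pseudomonas", "Burkholderia",
      "Bradyrhizobium", "Methylobacterium", "Delftia", "Acinetobacter",
      "Comamonas", "Stenotrophomonas", "Herbaspirillum", "Phyllobacterium")
  }
}
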