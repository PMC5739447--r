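# Model catalog: the 1965 4-node and present-day 7-node central dogma
# Boolean models, plus the probabilistic mixture of the present-day
# activatory and inhibitory variants.

.CD1965_NODES <- c("Activator", "DNA", "mRNA", "Protein")
.CD_NODES <- c("Activator", "DegProtein", "DegRNA", "DNA", "miRNA", "mRNA",
               "Protein")

.CD_DESCRIPTIONS <- c(
  V1 = "Activatory",
  V2 = "mRNA expression inhibition",
  V3 = "miRNA expression inhibition",
  V4 = "Gene silencing",
  V5 = "Gene silencing & mRNA expression inhibition",
  V6 = "Gene silencing & miRNA expression inhibition",
  V7 = "miRNA & mRNA expression inhibition",
  V8 = "Inhibitory"
)

# version -> (proteinInhibitsMRNA, proteinInhibitsMiRNA, mirnaSilencesDNA)
.CD_VERSION_FLAGS <- list(
  V1 = c(0L, 0L, 0L), V2 = c(1L, 0L, 0L), V3 = c(0L, 1L, 0L),
  V4 = c(0L, 0L, 1L), V5 = c(1L, 0L, 1L), V6 = c(0L, 1L, 1L),
  V7 = c(1L, 1L, 0L), V8 = c(1L, 1L, 1L)
)

#' Construct a present-day central dogma model variant
#'
#' The 7-node present-day model has three signed functional
#' relationships, each of which can be activatory or inhibitory:
#' Protein on mRNA transcription, Protein on miRNA transcription, and
#' miRNA on DNA (gene silencing). The eight sign combinations give the
#' catalog versions V1 (all activatory) through V8 (all inhibitory).
#'
#' @param proteinInhibitsMRNA Flip the Protein literal in the mRNA rule
#'   to `!Protein`.
#' @param proteinInhibitsMiRNA Flip the Protein literal in the miRNA
#'   rule to `!Protein`.
#' @param mirnaSilencesDNA Flip the miRNA literal in the DNA rule to
#'   `!miRNA` (miRNA-mediated gene silencing).
#' @param name Optional model label; defaults to the catalog id when the
#'   flags match a catalog version.
#' @return A deterministic 7-node [BooleanNetwork-class] with node order
#'   Activator, DegProtein, DegRNA, DNA, miRNA, mRNA, Protein.
#' @examples
#' identicalRules <- function(a, b) identical(transitionTable(a), transitionTable(b))
#' identicalRules(buildCDModel(FALSE, FALSE, FALSE), cdModel("CD-V1"))
#' @export
buildCDModel <- function(proteinInhibitsMRNA = FALSE,
                         proteinInhibitsMiRNA = FALSE,
                         mirnaSilencesDNA = FALSE,
                         name = NULL) {
  flags <- as.integer(c(proteinInhibitsMRNA, proteinInhibitsMiRNA,
                        mirnaSilencesDNA))
  if (is.null(name)) {
    hit <- Filter(function(v) identical(.CD_VERSION_FLAGS[[v]], flags),
                  names(.CD_VERSION_FLAGS))
    name <- if (length(hit)) paste0("CD-", hit[[1L]])
            else sprintf("CD(%d,%d,%d)", flags[1], flags[2], flags[3])
  }
  booleanNetwork(name, .CD_NODES, list(
    Activator = "Protein | Activator",
    DegProtein = "Protein &! DegProtein",
    DegRNA = "miRNA & Protein &! DegProtein",
    DNA = if (flags[3L]) "(!miRNA & Protein) | DNA"
          else "(miRNA & Protein) | DNA",
    miRNA = if (flags[2L]) "(DNA &! Protein | mRNA) &! DegRNA"
            else "(DNA & Protein | mRNA) &! DegRNA",
    mRNA = if (flags[1L]) "DNA &! Protein &! DegRNA"
           else "DNA & Protein &! DegRNA",
    Protein = "(mRNA & Activator | Protein) &! DegProtein"
  ))
}

.build1965Model <- function(inhibitory) {
  booleanNetwork(if (inhibitory) "CD1965-V2" else "CD1965-V1", .CD1965_NODES,
    list(
      Activator = "Activator",
      DNA = "DNA",
      mRNA = if (inhibitory) "DNA &! Protein" else "DNA & Protein",
      Protein = "(mRNA & Activator) | Protein"
    ))
}

.buildCDPBN <- function() {
  booleanNetwork("CD-PBN", .CD_NODES, list(
    Activator = "Protein | Activator",
    DegProtein = "Protein &! DegProtein",
    DegRNA = "miRNA & Protein &! DegProtein",
    DNA = list(
      list(rule = "(miRNA & Protein) | DNA", prob = 0.1),
      list(rule = "(!miRNA & Protein) | DNA", prob = 0.9)
    ),
    miRNA = list(
      list(rule = "(DNA & Protein | mRNA) &! DegRNA", prob = 0.8),
      list(rule = "(DNA &! Protein | mRNA) &! DegRNA", prob = 0.2)
    ),
    mRNA = list(
      list(rule = "DNA & Protein &! DegRNA", prob = 0.8),
      list(rule = "DNA &! Protein &! DegRNA", prob = 0.2)
    ),
    Protein = "(mRNA & Activator | Protein) &! DegProtein"
  ))
}

#' Catalog model identifiers
#'
#' @return Character vector of the eleven catalog ids: `CD1965-V1`,
#'   `CD1965-V2` (4-node 1965 models), `CD-V1` ... `CD-V8` (present-day
#'   sign variants) and `CD-PBN` (the probabilistic mixture of CD-V1 and
#'   CD-V8 rules).
#' @export
cdModelIds <- function() {
  c("CD1965-V1", "CD1965-V2", paste0("CD-", names(.CD_DESCRIPTIONS)), "CD-PBN")
}

#' Retrieve a catalog central dogma model
#'
#' @param id A catalog id, see [cdModelIds()].
#' @return A freshly constructed [BooleanNetwork-class]; modifying it
#'   cannot affect the catalog.
#' @examples
#' cdModel("CD1965-V1")
#' networkNodes(cdModel("CD-V1"))
#' @export
cdModel <- function(id) {
  stopifnot(is.character(id), length(id) == 1L)
  if (!id %in% cdModelIds()) {
    stop(sprintf("unknown model id '%s'; valid ids: %s",
                 id, paste(cdModelIds(), collapse = ", ")), call. = FALSE)
  }
  if (id == "CD1965-V1") return(.build1965Model(FALSE))
  if (id == "CD1965-V2") return(.build1965Model(TRUE))
  if (id == "CD-PBN") return(.buildCDPBN())
  flags <- .CD_VERSION_FLAGS[[sub("^CD-", "", id)]]
  buildCDModel(flags[1L] == 1L, flags[2L] == 1L, flags[3L] == 1L, name = id)
}

#' Human-readable description of a catalog model
#'
#' @param id A catalog id.
#' @return One-line description (the variant's system name).
#' @export
cdModelDescription <- function(id) {
  descs <- c(
    "CD1965-V1" = "1965 model, activatory gene expression",
    "CD1965-V2" = "1965 model, inhibitory gene expression",
    setNames(paste("Present-day model,", unname(.CD_DESCRIPTIONS)),
             paste0("CD-", names(.CD_DESCRIPTIONS))),
    "CD-PBN" = "Present-day model, probabilistic mixture of V1 and V8 rules"
  )
  if (!id %in% names(descs)) {
    stop(sprintf("unknown model id '%s'", id), call. = FALSE)
  }
  unname(descs[id])
}
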