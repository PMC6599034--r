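# Drug-response screen: responder classification by maximum screening
# concentration, mutant/wild-type stratification by gene pairs (or single
# genes with variant classifications), and the perfect-separation search.

#' Classify IC50 values as responder / non-responder
#'
#' A cell line is a responder to a drug when its IC50 is strictly below the
#' drug's maximum screening concentration; an IC50 equal to or above the
#' maximum screening concentration is non-responder (ties fall on the
#' conservative, non-responder side). Missing IC50s stay \code{NA}.
#'
#' @param ic50 numeric vector of IC50 values (> 0; NAs allowed)
#' @param maxConc the drug's maximum screening concentration (single
#'   positive number)
#' @return character vector \code{"responder"} / \code{"non_responder"} /
#'   \code{NA}
#' @examples
#' classifyResponse(c(0.5, 2, 1, NA), maxConc = 1)
#' @export
classifyResponse <- function(ic50, maxConc) {
  if (length(maxConc) != 1 || is.na(maxConc) || maxConc <= 0)
    stop("maxConc must be a single positive number")
  if (any(ic50 <= 0, na.rm = TRUE)) stop("ic50 values must be positive")
  ifelse(is.na(ic50), NA_character_,
         ifelse(ic50 < maxConc, "responder", "non_responder"))
}

#' Stratify cell lines by mutations in a gene pair
#'
#' Mutant group: lines with a mutation in either gene of the pair.
#' Wild-type group: lines without any mutation in both genes.
#'
#' @param screen a [DrugScreenTable-class]
#' @param geneA,geneB gene names present in the mutation matrix
#' @return list with character vectors \code{mutant} and \code{wildtype}
#' @export
stratifyByPair <- function(screen, geneA, geneB) {
  stopifnot(is(screen, "DrugScreenTable"))
  mm <- screen@mutations
  for (g in c(geneA, geneB))
    if (!g %in% colnames(mm)) stop("gene not in mutation matrix: ", g)
  mut <- mm[, geneA] == 1 | mm[, geneB] == 1
  list(mutant = rownames(mm)[mut], wildtype = rownames(mm)[!mut])
}

#' Search for drugs that perfectly separate mutant and wild-type groups
#'
#' For every gene pair and drug, cell lines are stratified by the pair and
#' classified by the drug's maximum screening concentration (lines with a
#' missing IC50 for that drug are excluded). A hit is emitted only on
#' perfect, non-overlapping separation with both groups non-empty: all
#' mutant lines responders and all wild-type lines non-responders
#' (\code{direction = "mutant_responsive"}), or the reverse
#' (\code{"wildtype_responsive"}).
#'
#' @param screen a [DrugScreenTable-class]
#' @param pairs a two-column matrix/data.frame of gene names, or a list of
#'   length-2 character vectors
#' @return data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{drug}, \code{direction}, \code{n_mutant}, \code{n_wildtype}
#'   (zero rows when nothing separates)
#' @export
findSeparatingDrugs <- function(screen, pairs) {
  stopifnot(is(screen, "DrugScreenTable"))
  if (is.list(pairs) && !is.data.frame(pairs))
    pairs <- do.call(rbind, pairs)
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2 || nrow(pairs) < 1)
    stop("pairs must provide at least one gene pair")
  drugs <- colnames(screen@ic50)
  if (length(drugs) < 1) stop("screen contains no drugs")
  hits <- list()
  for (i in seq_len(nrow(pairs))) {
    grp <- stratifyByPair(screen, pairs[i, 1], pairs[i, 2])
    if (length(grp$mutant) == 0 || length(grp$wildtype) == 0) {
      warning("pair ", pairs[i, 1], "/", pairs[i, 2],
              " leaves an empty group; skipped")
      next
    }
    for (d in drugs) {
      cls <- classifyResponse(screen@ic50[, d], screen@maxConc[[d]])
      names(cls) <- rownames(screen@ic50)
      mcls <- cls[grp$mutant]; wcls <- cls[grp$wildtype]
      mcls <- mcls[!is.na(mcls)]; wcls <- wcls[!is.na(wcls)]
      if (length(mcls) == 0 || length(wcls) == 0) next
      dir <- if (all(mcls == "responder") && all(wcls == "non_responder"))
        "mutant_responsive"
      else if (all(mcls == "non_responder") && all(wcls == "responder"))
        "wildtype_responsive"
      else NA_character_
      if (!is.na(dir)) {
        hits[[length(hits) + 1]] <- data.frame(
          gene_a = pairs[i, 1], gene_b = pairs[i, 2], drug = d,
          direction = dir, n_mutant = length(mcls),
          n_wildtype = length(wcls), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      drug = character(0), direction = character(0),
                      n_mutant = integer(0), n_wildtype = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

.SILENT_CLASSES <- c("Silent", "synonymous")
.KNOWN_CLASSES <- c(.SILENT_CLASSES, "Missense_Mutation",
                    "Nonsense_Mutation", "Nonstop_Mutation", "Splice_Site",
                    "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del",
                    "In_Frame_Ins", "Translation_Start_Site")

#' Stratify samples by non-silent mutation status of a single gene
#'
#' Mutant group: samples with at least one non-silent mutation call for the
#' gene. Wild-type group: samples with no mutation call at all for the
#' gene. Samples whose only calls are silent satisfy neither criterion and
#' are excluded. Unknown variant-classification strings are treated as
#' non-silent (and reported).
#'
#' @param calls data.frame of mutation calls with columns \code{sample},
#'   \code{gene}, \code{variant_classification}
#' @param gene the gene to stratify by
#' @param samples the full sample universe (default: all samples appearing
#'   in \code{calls}); samples outside \code{calls} are wild-type
#' @return list with character vectors \code{mutant}, \code{wildtype},
#'   \code{excluded}
#' @export
stratifyByMutation <- function(calls, gene,
                               samples = unique(calls$sample)) {
  need <- c("sample", "gene", "variant_classification")
  if (!all(need %in% names(calls)))
    stop("calls must have columns sample, gene, variant_classification")
  gc <- calls[calls$gene == gene, , drop = FALSE]
  unknown <- setdiff(unique(gc$variant_classification), .KNOWN_CLASSES)
  for (u in unknown)
    message("unknown variant classification treated as non-silent: ", u)
  nonSilent <- !(gc$variant_classification %in% .SILENT_CLASSES)
  mutant <- unique(gc$sample[nonSilent])
  anyCall <- unique(gc$sample)
  wildtype <- setdiff(samples, anyCall)
  excluded <- setdiff(anyCall, mutant)
  list(mutant = intersect(samples, mutant), wildtype = wildtype,
       excluded = intersect(samples, excluded))
}

#' Read a drug screen from three tab-delimited tables
#'
#' @param ic50Path TSV, cell lines in rows (first column), drugs in columns
#' @param maxConcPath TSV with columns \code{drug}, \code{max_conc}
#' @param mutationsPath TSV, cell lines in rows (first column), genes in
#'   columns, entries 0/1
#' @return a [DrugScreenTable-class]
#' @export
readDrugScreen <- function(ic50Path, maxConcPath, mutationsPath) {
  ic <- as.matrix(read.delim(ic50Path, row.names = 1, check.names = FALSE))
  mx <- read.delim(maxConcPath, check.names = FALSE)
  if (!all(c("drug", "max_conc") %in% names(mx)))
    stop("max-conc table must have columns drug, max_conc")
  mu <- as.matrix(read.delim(mutationsPath, row.names = 1,
                             check.names = FALSE))
  new("DrugScreenTable", ic50 = ic,
      maxConc = stats::setNames(mx$max_conc, mx$drug),
      mutations = mu[rownames(ic), , drop = FALSE])
}

#' Write a drug screen as three tab-delimited tables
#'
#' @param screen a [DrugScreenTable-class]
#' @param ic50Path,maxConcPath,mutationsPath output paths (see
#'   [readDrugScreen()] for the layouts)
#' @return invisibly, the three paths
#' @export
writeDrugScreen <- function(screen, ic50Path, maxConcPath, mutationsPath) {
  stopifnot(is(screen, "DrugScreenTable"))
  wr <- function(m, path) {
    df <- data.frame(cell_line = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr(screen@ic50, ic50Path)
  write.table(data.frame(drug = names(screen@maxConc),
                         max_conc = unname(screen@maxConc)),
              maxConcPath, sep = "\t", quote = FALSE, row.names = FALSE)
  wr(screen@mutations, mutationsPath)
  invisible(c(ic50Path, maxConcPath, mutationsPath))
}
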