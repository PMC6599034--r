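# Readers and writers for the tab-delimited formats the workflow consumes:
# Pathway Commons-style extended SIF, GMT gene sets, seed lists and
# subnetwork output tables.

.SIF_COLS <- c("PARTICIPANT_A", "INTERACTION_TYPE", "PARTICIPANT_B",
               "PATHWAY_NAMES")

#' Read a pathway-annotated interaction network from extended SIF
#'
#' Parses the tab-delimited pairwise-interaction dialect used by Pathway
#' Commons exports of curated pathway databases: columns participant A,
#' interaction type, participant B and an optional semicolon-separated
#' pathway-names column. A header line is auto-detected by the literal
#' string \code{"PARTICIPANT_A"}; without a header the first three (four)
#' columns are taken positionally. Direction is discarded (A-B and B-A rows
#' merge, pathway sets unioned), duplicate rows merge, and self-loop rows
#' are skipped with a warning.
#'
#' @param path path to a tab-delimited file
#' @return a [PathwayNetwork-class]
#' @examples
#' f <- tempfile()
#' writeLines(c("A\tin-complex-with\tB\tP1", "B\tin-complex-with\tC\tP1;P2"), f)
#' net <- readExtendedSIF(f)
#' pathwayMembers(net)
#' @export
readExtendedSIF <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty extended-SIF file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  hasHeader <- grepl("PARTICIPANT_A", lines[1], fixed = TRUE)
  if (hasHeader) {
    hdr <- trimws(fields[[1]])
    for (col in .SIF_COLS[1:3])
      if (!col %in% hdr)
        stop("extended-SIF header is missing required column '", col, "'")
    ia <- match("PARTICIPANT_A", hdr)
    it <- match("INTERACTION_TYPE", hdr)
    ib <- match("PARTICIPANT_B", hdr)
    ip <- match("PATHWAY_NAMES", hdr)
    fields <- fields[-1]
  } else {
    ia <- 1L; it <- 2L; ib <- 3L; ip <- 4L
  }
  if (length(fields) == 0) stop("extended-SIF file has no data rows: ", path)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("extended-SIF rows with fewer than 3 columns (first at data row ",
         which(nf < 3)[1], ")")
  a <- vapply(fields, function(x) trimws(x[ia]), "")
  b <- vapply(fields, function(x) trimws(x[ib]), "")
  int <- vapply(fields, function(x) trimws(x[it]), "")
  pw <- lapply(fields, function(x) {
    if (is.na(ip) || length(x) < ip || !nzchar(trimws(x[ip])))
      return(character(0))
    unique(trimws(strsplit(x[ip], ";", fixed = TRUE)[[1]]))
  })
  if (any(!nzchar(a) | !nzchar(b)))
    stop("extended-SIF rows with empty participant symbols")
  .buildNetwork(a, b, int, pw)
}

#' Write a network (or subnetwork graph) as extended SIF
#'
#' @param network a [PathwayNetwork-class]
#' @param path output path
#' @param header write the column header line (default TRUE)
#' @return invisibly, the path
#' @export
writeExtendedSIF <- function(network, path, header = TRUE) {
  et <- edgeTable(network)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (header) writeLines(paste(.SIF_COLS, collapse = "\t"), con)
  if (nrow(et) > 0) {
    writeLines(paste(et$from, et$interaction, et$to, et$pathways,
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, \code{name TAB description TAB gene...}.
#' Duplicate genes within a line are collapsed.
#'
#' @param path path to a GMT file
#' @return named list mapping pathway name to a character vector of genes
#' @export
readGMT <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty GMT file: ", path)
    return(list())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3
  if (any(short))
    stop("GMT line ", which(short)[1], " has fewer than 3 fields")
  out <- lapply(fields, function(x) unique(trimws(x[-(1:2)])))
  names(out) <- vapply(fields, `[[`, "", 1L)
  out
}

#' Map requested gene symbols onto a network as a seed set
#'
#' Exact, case-sensitive matching; symbols absent from the network are
#' reported individually and kept in the \code{dropped} slot.
#'
#' @param network a [PathwayNetwork-class]
#' @param symbols character vector of gene symbols (duplicates collapsed)
#' @return a [SeedSet-class]; error if no symbol maps
#' @export
mapSeeds <- function(network, symbols) {
  requested <- unique(as.character(symbols))
  requested <- requested[nzchar(requested)]
  present <- requested %in% geneNames(network)
  dropped <- requested[!present]
  for (s in dropped) message("seed gene not in network, dropped: ", s)
  if (!any(present)) stop("no seed genes found in network")
  new("SeedSet", requested = requested, mapped = requested[present],
      dropped = dropped)
}

#' Read a seed gene list and map it onto a network
#'
#' One symbol per line; blank lines and lines starting with \code{#} are
#' ignored; duplicates collapse to one seed.
#'
#' @param path path to a plain-text seed list
#' @param network the [PathwayNetwork-class] to map against
#' @return a [SeedSet-class]; error if no symbol maps
#' @export
readSeedList <- function(path, network) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  mapSeeds(network, lines)
}

#' Write a subnetwork as a SIF file plus a node table
#'
#' The SIF carries the induced edges with their pathway annotations; the
#' node table is tab-delimited with columns \code{gene}, \code{is_seed},
#' \code{f}, \code{p}, \code{q} (seeds have f = 1 and no p/q).
#'
#' @param subnetwork a [Subnetwork-class]
#' @param sifPath output path for the edge SIF
#' @param nodeTablePath output path for the node table
#' @return invisibly, \code{c(sifPath, nodeTablePath)}
#' @export
writeSubnetwork <- function(subnetwork, sifPath, nodeTablePath) {
  writeExtendedSIF(subnetwork@network, sifPath)
  genes <- geneNames(subnetwork)
  isSeed <- genes %in% subnetwork@seeds@mapped
  st <- subnetwork@significance@table
  i <- match(genes, st$gene)
  nt <- data.frame(gene = genes, is_seed = isSeed,
                   f = ifelse(isSeed, 1, st$f[i]),
                   p = ifelse(isSeed, NA_real_, st$p[i]),
                   q = ifelse(isSeed, NA_real_, st$q[i]),
                   stringsAsFactors = FALSE)
  write.table(nt, nodeTablePath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(sifPath, nodeTablePath))
}
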