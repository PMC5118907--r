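# Tab-separated interchange formats: expression (first column feature id,
# header row sample ids), sample annotation (sample/phenotype/batch), probe
# map (probe/symbol, empty symbol = unmapped), edge lists
# (source/target/mi/p_value). Numeric values are written with 17 significant
# digits so a write/read round trip is exact.

.check_fields <- function(file, expected) {
  nf <- utils::count.fields(file, sep = "\t", quote = "", comment.char = "")
  bad <- which(nf != expected)
  if (length(bad))
    stop("malformed row in '", basename(file), "' at line ", bad[1],
         ": expected ", expected, " fields, found ", nf[bad[1]])
}

#' Write / read an expression matrix
#'
#' @param em an [ExpressionMatrix-class] object.
#' @param file path of the expression TSV.
#' @param annotation_file path of the sample annotation TSV
#'   (sample, phenotype, batch).
#' @return `writeExpression` invisibly returns the paths;
#'   `readExpression` returns an [ExpressionMatrix-class].
#' @export
writeExpression <- function(em, file, annotation_file) {
  v <- exprsValues(em)
  body <- cbind(feature_id = rownames(v),
                matrix(.fmt_num(v), nrow(v), ncol(v)))
  colnames(body) <- c("feature_id", colnames(v))
  utils::write.table(body, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ann <- data.frame(sample = colnames(v),
                    phenotype = unname(phenotypeLabels(em)),
                    batch = unname(batchLabels(em)))
  utils::write.table(ann, annotation_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(file, annotation_file))
}

#' @rdname writeExpression
#' @export
readExpression <- function(file, annotation_file) {
  header <- strsplit(readLines(file, n = 1), "\t", fixed = TRUE)[[1]]
  .check_fields(file, length(header))
  tab <- utils::read.table(file, sep = "\t", header = TRUE,
                           check.names = FALSE, quote = "",
                           colClasses = c("character",
                                          rep("numeric",
                                              length(header) - 1)))
  if (anyDuplicated(tab[[1]]))
    stop("duplicate feature ids in '", basename(file), "': ",
         tab[[1]][anyDuplicated(tab[[1]])][1])
  v <- as.matrix(tab[, -1, drop = FALSE])
  rownames(v) <- tab[[1]]
  ann <- utils::read.table(annotation_file, sep = "\t", header = TRUE,
                           quote = "", colClasses = "character")
  if (anyDuplicated(ann$sample)) stop("duplicate sample ids in annotation")
  if (!setequal(ann$sample, colnames(v)))
    stop("annotation samples do not match expression columns")
  ann <- ann[match(colnames(v), ann$sample), ]
  ExpressionMatrix(v, phenotype = ann$phenotype, batch = ann$batch)
}

#' Write / read a probe-to-gene map
#'
#' @param map data.frame `probe`, `symbol` (NA symbol = unmapped).
#' @param file path of the two-column TSV.
#' @return `readProbeMap` returns the map data.frame.
#' @export
writeProbeMap <- function(map, file) {
  out <- data.frame(probe = map$probe,
                    symbol = ifelse(is.na(map$symbol), "", map$symbol))
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname writeProbeMap
#' @export
readProbeMap <- function(file) {
  tab <- utils::read.table(file, sep = "\t", header = TRUE, quote = "",
                           colClasses = "character", fill = TRUE)
  tab$symbol[tab$symbol == ""] <- NA_character_
  if (anyDuplicated(tab$probe)) stop("duplicate probes in map")
  tab
}

#' Write / read an edge list
#'
#' Edge lists are written sorted by descending MI with header
#' `source target mi p_value`; reading validates the rows (self-loops and
#' duplicate pairs are rejected with their line number).
#'
#' @param interactions data.frame with `feature_a`/`feature_b` (or
#'   `source`/`target`), `mi`, optional `p_value`.
#' @param file TSV path.
#' @return `readEdges` returns a data.frame `feature_a`, `feature_b`,
#'   `mi`, `p_value`.
#' @export
writeEdges <- function(interactions, file) {
  a <- interactions[[1]]; b <- interactions[[2]]
  mi <- interactions$mi
  p <- if ("p_value" %in% colnames(interactions))
    interactions$p_value else rep(NA_real_, length(a))
  o <- order(-mi, a, b, method = "radix")
  out <- data.frame(source = a[o], target = b[o], mi = .fmt_num(mi[o]),
                    p_value = ifelse(is.na(p[o]), "NA", .fmt_num(p[o])))
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname writeEdges
#' @export
readEdges <- function(file) {
  .check_fields(file, 4L)
  tab <- utils::read.table(file, sep = "\t", header = TRUE, quote = "",
                           colClasses = c("character", "character",
                                          "numeric", "numeric"))
  self <- which(tab$source == tab$target)
  if (length(self))
    stop("self-loop in '", basename(file), "' at line ", self[1] + 1L)
  key <- pairKey(tab$source, tab$target)
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate pair in '", basename(file), "' at line ", dup[1] + 1L)
  data.frame(feature_a = tab$source, feature_b = tab$target, mi = tab$mi,
             p_value = tab$p_value, stringsAsFactors = FALSE)
}

#' Export a network in SIF format
#'
#' One `source <tab> mi <tab> target` line per edge, for import into
#' network visualization tools.
#'
#' @param net a [GeneNetwork-class] object.
#' @param file output path.
#' @export
writeSIF <- function(net, file) {
  e <- edgeTable(net)
  writeLines(sprintf("%s\tmi\t%s", e$source, e$target), file)
  invisible(file)
}

#' Export a network in GraphML format
#'
#' @param net a [GeneNetwork-class] object.
#' @param file output path.
#' @export
writeGraphML <- function(net, file) {
  igraph::write_graph(.as_igraph(net), file, format = "graphml")
  invisible(file)
}
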