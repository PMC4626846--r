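#' Construct an OTU count table
#'
#' The basic container of the pipeline: an integer count matrix with one row
#' per OTU and one column per sample, plus a taxonomy lineage string per OTU
#' and a free-text body-site label.
#'
#' @param counts non-negative integer matrix, rows = OTUs, columns = samples.
#' @param otu_ids unique character identifiers, one per row of `counts`.
#' @param lineages taxonomy lineage string per OTU (Greengenes-style
#'   `k__...;p__...;...` or plain semicolon-delimited names).
#' @param site body-site label attached to the table.
#' @return An object of class `otu_table`: a list with elements `counts`
#'   (matrix with `otu_ids` as rownames), `lineages` (named by OTU id) and
#'   `site`.
#' @examples
#' tab <- otu_table(matrix(0:5, 3, 2), c("otu1", "otu2", "otu3"),
#'                  rep("k__Bacteria;g__Dorea", 3), site = "stool")
#' n_otus(tab)
#' @export
otu_table <- function(counts, otu_ids, lineages, site = "unknown") {
  counts <- as.matrix(counts)
  if (length(otu_ids) != nrow(counts) || length(lineages) != nrow(counts))
    stop("otu_ids, lineages and rows of counts must have equal length")
  if (anyDuplicated(otu_ids))
    stop("duplicate OTU ids: ",
         paste(unique(otu_ids[duplicated(otu_ids)]), collapse = ", "))
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "double"   # keeps exact integers, avoids overflow
  rownames(counts) <- otu_ids
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  structure(
    list(counts = counts, lineages = stats::setNames(as.character(lineages),
                                                     otu_ids),
         site = site),
    class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d OTUs x %d samples (site: %s)\n",
              nrow(x$counts), ncol(x$counts), x$site))
  invisible(x)
}

#' @rdname otu_table
#' @param x an `otu_table`.
#' @export
n_otus <- function(x) nrow(x$counts)

#' @rdname otu_table
#' @export
n_samples <- function(x) ncol(x$counts)

#' Read an OTU table from classic tab-separated text
#'
#' Expects one header row of sample ids, a first column of OTU ids, and a
#' column named `taxonomy` (case-insensitive, any position after the first)
#' holding the lineage string; all remaining columns are integer counts.
#' Lines starting with `#` before the header (BIOM-style preamble) are
#' skipped, except that a final `#OTU ID ...` line is accepted as the header.
#'
#' @param path path to a TSV file.
#' @param site body-site label to attach.
#' @return An [otu_table].
#' @export
read_otu_table <- function(path, site = "unknown") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  # drop comment preamble but keep a '#OTU ID' header line
  is_comment <- startsWith(lines, "#") & !grepl("^#\\s*OTU", lines, ignore.case = TRUE)
  lines <- lines[!is_comment]
  if (length(lines) < 2) stop("no OTUs in ", path)
  d <- utils::read.table(text = lines, sep = "\t", header = TRUE,
                         check.names = FALSE, comment.char = "",
                         colClasses = "character", quote = "")
  if (nrow(d) == 0) stop("no OTUs in ", path)
  tax_col <- which(tolower(trimws(colnames(d))) %in%
                     c("taxonomy", "lineage", "consensus lineage"))
  if (length(tax_col) != 1)
    stop("expected exactly one taxonomy column in ", path)
  otu_ids <- trimws(d[[1]])
  lineages <- d[[tax_col]]
  count_cols <- setdiff(seq_len(ncol(d))[-1], tax_col)
  if (length(count_cols) == 0) stop("no sample columns in ", path)
  raw <- as.matrix(d[count_cols])
  num <- suppressWarnings(matrix(as.numeric(raw), nrow(raw), ncol(raw)))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-integer or negative count for OTU '%s' (line %d), sample '%s'",
                 otu_ids[bad[1, 1]], bad[1, 1] + 1L,
                 colnames(d)[count_cols][bad[1, 2]]))
  colnames(num) <- colnames(d)[count_cols]
  otu_table(num, otu_ids, lineages, site = site)
}

#' Write an OTU table in the same TSV dialect [read_otu_table] accepts
#'
#' @param table an [otu_table].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path) {
  d <- data.frame(`#OTU ID` = rownames(table$counts), table$counts,
                  taxonomy = unname(table$lineages),
                  check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# rank prefixes from kingdom down to species, most specific last
.rank_order <- c(k = "kingdom", p = "phylum", c = "class", o = "order",
                 f = "family", g = "genus", s = "species")

#' Parse a taxonomy lineage into a group label
#'
#' Returns the most specific named rank at or above genus: the genus if it is
#' named, otherwise the family, then order, and so on. Species-level names are
#' never used as the group, because OTU groups of interest (the rows of a
#' group-enrichment table) mix genera, families and orders. Accepts
#' Greengenes-style rank-prefixed lineages (`k__Bacteria;...;g__Dorea`) or
#' plain semicolon-delimited names (in which case a 7th field is taken to be
#' the species and ignored).
#'
#' @param lineage character vector of lineage strings.
#' @return character vector of group labels; empty lineages give
#'   `"Unclassified"`.
#' @examples
#' parse_group("k__Bacteria;f__Ruminococcaceae;g__Faecalibacterium")
#' parse_group("k__Bacteria;f__Lachnospiraceae;g__")
#' @export
parse_group <- function(lineage) {
  vapply(lineage, function(lin) {
    parts <- trimws(strsplit(lin, ";", fixed = TRUE)[[1]])
    if (length(parts) > 0 && all(grepl("^[kpcofgs]__", parts))) {
      names(parts) <- substr(parts, 1, 1)
      parts <- sub("^[kpcofgs]__", "", parts)
      parts <- parts[names(parts) != "s"]
      keep <- names(.rank_order)[names(.rank_order) %in% names(parts)]
      parts <- parts[keep]          # kingdom -> genus order
    } else {
      if (length(parts) >= 7) parts <- parts[1:6]  # drop species field
    }
    parts <- parts[nzchar(parts)]
    if (length(parts) == 0) "Unclassified" else unname(parts[length(parts)])
  }, character(1), USE.NAMES = FALSE)
}

#' Map each OTU of a table to its taxonomic group
#'
#' @param table an [otu_table].
#' @param overrides optional data frame with columns `otu_id` and `group`
#'   (e.g. read from a two-column TSV) taking precedence over lineage parsing.
#' @return data frame with columns `otu_id` and `group`, one row per OTU of
#'   the table, in table order.
#' @export
group_map <- function(table, overrides = NULL) {
  g <- parse_group(unname(table$lineages))
  ids <- rownames(table$counts)
  if (!is.null(overrides)) {
    stopifnot(all(c("otu_id", "group") %in% colnames(overrides)))
    m <- match(ids, overrides$otu_id)
    g[!is.na(m)] <- overrides$group[m[!is.na(m)]]
  }
  if (any(!nzchar(g))) stop("empty group label")
  data.frame(otu_id = ids, group = g)
}

#' Prevalence filter: keep OTUs detected in at least a fraction of samples
#'
#' "Detected" means a strictly positive count. The boundary is inclusive: an
#' OTU present in exactly `theta` of the samples is kept. Samples whose total
#' count is zero are dropped (with a warning) before prevalence is computed.
#'
#' @param table an [otu_table].
#' @param theta minimum presence fraction in `[0, 1]`; default 0.20.
#' @return The filtered [otu_table]; OTU order is preserved.
#' @export
prevalence_filter <- function(table, theta = 0.20) {
  if (!is.numeric(theta) || length(theta) != 1 || theta < 0 || theta > 1)
    stop("theta must be a single number in [0, 1]")
  empty <- colSums(table$counts) == 0
  if (any(empty)) {
    warning(sum(empty), " sample(s) with zero total count dropped")
    table$counts <- table$counts[, !empty, drop = FALSE]
  }
  prev <- rowMeans(table$counts > 0)
  keep <- prev >= theta
  otu_table(table$counts[keep, , drop = FALSE],
            rownames(table$counts)[keep],
            table$lineages[keep], site = table$site)
}
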