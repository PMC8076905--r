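#' Construct an OTU count table
#'
#' An `otu_table` bundles an integer count matrix (OTUs in rows, samples in
#' columns) with a ranked taxonomy lineage per OTU and a domain tag. It is the
#' central container passed between rarefaction, stability assessment, the
#' phenotype screen and the co-occurrence analysis.
#'
#' @param counts non-negative integer matrix, OTUs x samples; must carry row
#'   and column names (OTU and sample identifiers).
#' @param taxonomy data.frame with one row per OTU and columns
#'   `domain, phylum, class, order, family, genus`; unassigned ranks are `NA`.
#'   May be `NULL`, in which case all ranks are unassigned.
#' @param domain_tag `"bacteria"` or `"archaea"`.
#' @return an object of class `otu_table`: a list with elements `counts`,
#'   `taxonomy`, `domain_tag`, `otu_ids`, `sample_ids`.
#' @export
otu_table <- function(counts, taxonomy = NULL, domain_tag = c("bacteria", "archaea")) {
  domain_tag <- match.arg(domain_tag)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have OTU row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate OTU identifiers")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample identifiers")
  if (!is.numeric(counts) || anyNA(counts))
    stop("counts must be numeric with no missing values")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "double"  # avoids integer overflow on column sums
  if (is.null(taxonomy)) {
    taxonomy <- empty_taxonomy(nrow(counts))
  } else {
    taxonomy <- as.data.frame(taxonomy, stringsAsFactors = FALSE)
    if (nrow(taxonomy) != nrow(counts))
      stop("taxonomy must have one row per OTU")
    missing_cols <- setdiff(tax_ranks(), names(taxonomy))
    if (length(missing_cols))
      stop("taxonomy lacks rank columns: ", paste(missing_cols, collapse = ", "))
    taxonomy <- taxonomy[, tax_ranks(), drop = FALSE]
  }
  rownames(taxonomy) <- rownames(counts)
  structure(
    list(counts = counts, taxonomy = taxonomy, domain_tag = domain_tag,
         otu_ids = rownames(counts), sample_ids = colnames(counts)),
    class = "otu_table")
}

tax_ranks <- function() c("domain", "phylum", "class", "order", "family", "genus")

empty_taxonomy <- function(n) {
  out <- as.data.frame(matrix(NA_character_, n, 6), stringsAsFactors = FALSE)
  names(out) <- tax_ranks()
  out
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d OTUs x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts), x$domain_tag))
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Parse a semicolon-separated lineage string
#'
#' Lineages follow the RDP convention
#' `Domain;Phylum;Class;Order;Family;Genus`; empty fields or fields equal to
#' "unassigned"/"unclassified" become `NA` (unassigned), they are never
#' dropped. Trailing ranks may be omitted entirely.
#'
#' @param lineages character vector of lineage strings.
#' @return data.frame with columns `domain ... genus`.
#' @export
parse_lineage <- function(lineages) {
  parts <- strsplit(as.character(lineages), ";", fixed = TRUE)
  mat <- t(vapply(parts, function(p) {
    p <- trimws(p)
    p <- c(p, rep("", 6L))[1:6]
    p[p == "" | tolower(p) %in% c("unassigned", "unclassified", "na")] <- NA_character_
    p
  }, character(6)))
  out <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(out) <- tax_ranks()
  out
}

#' Read an OTU table from TSV, with a taxonomy map
#'
#' The count file is TSV with the first column `otu_id` and one column per
#' sample; cells must be non-negative integers. The taxonomy file is a
#' two-column TSV mapping `otu_id` to a semicolon-separated lineage.
#'
#' @param path count TSV.
#' @param taxonomy_path optional lineage TSV; OTUs absent from it get fully
#'   unassigned lineages.
#' @param domain_tag `"bacteria"` or `"archaea"`.
#' @return [otu_table()]
#' @export
read_otu_table <- function(path, taxonomy_path = NULL, domain_tag = "bacteria") {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("count table needs an otu_id column plus >=1 sample")
  ids <- as.character(raw[[1]])
  counts <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(counts)) stop("non-numeric cell in count table")
  rownames(counts) <- ids
  taxonomy <- NULL
  if (!is.null(taxonomy_path)) {
    tx <- utils::read.delim(taxonomy_path, header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
    lin <- parse_lineage(tx[[2]])
    rownames(lin) <- as.character(tx[[1]])
    taxonomy <- empty_taxonomy(length(ids))
    hit <- match(ids, rownames(lin))
    taxonomy[!is.na(hit), ] <- lin[hit[!is.na(hit)], ]
  }
  otu_table(counts, taxonomy, domain_tag)
}

#' Write an OTU table (counts + taxonomy) as TSV
#'
#' @param x [otu_table()]
#' @param path count TSV destination.
#' @param taxonomy_path optional lineage TSV destination.
#' @export
write_otu_table <- function(x, path, taxonomy_path = NULL) {
  df <- data.frame(otu_id = x$otu_ids, x$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(taxonomy_path)) {
    lin <- apply(x$taxonomy, 1, function(r) paste(ifelse(is.na(r), "", r), collapse = ";"))
    utils::write.table(data.frame(otu_id = x$otu_ids, lineage = lin),
                       taxonomy_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Rarefy samples to a common depth
#'
#' Each sample is subsampled without replacement to exactly `depth` reads
#' (classic single rarefaction), which normalizes sequencing effort before
#' diversity, stability and screening analyses. Samples whose total is below
#' `depth` are dropped; the ids of dropped samples are attached as the
#' `"dropped"` attribute and reported in a message, mirroring the exclusion of
#' under-sequenced samples in practice.
#'
#' @param x [otu_table()]
#' @param depth target reads per sample (e.g. 76000 for bacteria, 70000 for
#'   archaea).
#' @param seed integer seed; the draw is deterministic given the seed and does
#'   not disturb the caller's RNG state.
#' @return rarefied [otu_table()] with attribute `dropped`.
#' @export
rarefy <- function(x, depth, seed = 1L) {
  stopifnot(inherits(x, "otu_table"), depth > 0)
  depth <- as.integer(depth)
  totals <- colSums(x$counts)
  keep <- totals >= depth
  if (!any(keep))
    stop("rarefaction depth ", depth, " exceeds every sample total; drops: ",
         paste(x$sample_ids, collapse = ", "))
  if (any(!keep))
    message("rarefy: dropped ", sum(!keep), " sample(s) below depth ", depth, ": ",
            paste(x$sample_ids[!keep], collapse = ", "))
  out <- x$counts[, keep, drop = FALSE]
  withr::with_seed(seed, {
    for (j in seq_len(ncol(out))) {
      v <- out[, j]
      reads <- rep.int(seq_along(v), v)
      picked <- sample(reads, depth)
      out[, j] <- tabulate(picked, nbins = length(v))
    }
  })
  res <- otu_table(out, x$taxonomy, x$domain_tag)
  attr(res, "dropped") <- x$sample_ids[!keep]
  res
}

#' Per-sample relative abundances
#'
#' @param x [otu_table()] or a non-negative numeric matrix (taxa x samples).
#' @return matrix of fractions; every column sums to 1.
#' @export
relative_abundance <- function(x) {
  m <- if (inherits(x, "otu_table")) x$counts else as.matrix(x)
  totals <- colSums(m)
  if (any(totals <= 0)) stop("zero-total sample(s): ",
                             paste(colnames(m)[totals <= 0], collapse = ", "))
  sweep(m, 2, totals, "/")
}

#' Aggregate counts to a taxonomic rank
#'
#' OTU counts are summed over all OTUs sharing the lineage down to `rank`.
#' OTUs unassigned at `rank` are pooled under `unclassified_<deepest assigned
#' taxon>` (e.g. an OTU known only to family Prevotellaceae appears at genus
#' level as `unclassified_Prevotellaceae`). Total counts are conserved.
#'
#' @param x [otu_table()]
#' @param rank one of `"phylum"`, `"class"`, `"order"`, `"family"`, `"genus"`.
#' @return [otu_table()] whose rows are taxa at `rank`.
#' @export
collapse_taxonomy <- function(x, rank = c("phylum", "class", "order", "family", "genus")) {
  rank <- match.arg(rank)
  ranks <- tax_ranks()
  ri <- match(rank, ranks)
  tx <- x$taxonomy
  labels <- character(nrow(tx))
  for (i in seq_len(nrow(tx))) {
    if (!is.na(tx[i, ri])) {
      labels[i] <- tx[i, ri]
    } else {
      assigned <- which(!is.na(unlist(tx[i, seq_len(ri)])))
      deepest <- if (length(assigned)) tx[i, max(assigned)] else "unknown"
      labels[i] <- paste0("unclassified_", deepest)
    }
  }
  groups <- split(seq_len(nrow(tx)), labels)
  counts <- t(vapply(groups, function(idx)
    colSums(x$counts[idx, , drop = FALSE]), numeric(ncol(x$counts))))
  colnames(counts) <- x$sample_ids
  # lineage of each aggregate: ranks above `rank` from its first member,
  # blanked where members disagree; ranks below are unassigned
  taxonomy <- empty_taxonomy(length(groups))
  for (g in seq_along(groups)) {
    sub <- tx[groups[[g]], seq_len(ri), drop = FALSE]
    for (k in seq_len(ri)) {
      u <- unique(sub[[k]])
      if (length(u) == 1L) taxonomy[g, k] <- u
    }
  }
  otu_table(counts, taxonomy, x$domain_tag)
}

#' Bacteroidetes / Firmicutes ratio per sample
#'
#' The B/F ratio is a coarse index of the rumen community balance tracked
#' across lactation. Computed from phylum-collapsed counts; samples with zero
#' Firmicutes get `NA` and a warning.
#'
#' @param x [otu_table()] (OTU- or phylum-level).
#' @return data.frame `sample_id`, `bf_ratio`.
#' @export
bf_ratio <- function(x) {
  ph <- collapse_taxonomy(x, "phylum")
  b <- match("Bacteroidetes", ph$otu_ids)
  f <- match("Firmicutes", ph$otu_ids)
  if (is.na(b) || is.na(f))
    stop("Bacteroidetes and Firmicutes must both be present at phylum level")
  bac <- ph$counts[b, ]
  fir <- ph$counts[f, ]
  ratio <- ifelse(fir > 0, bac / fir, NA_real_)
  if (anyNA(ratio))
    warning("zero Firmicutes count in ", sum(is.na(ratio)), " sample(s); ratio undefined")
  data.frame(sample_id = ph$sample_ids, bf_ratio = as.numeric(ratio),
             stringsAsFactors = FALSE)
}
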