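#' Assign a lactation stage from days in milk
#'
#' Samples are grouped into early (DIM < 50), mid (50 <= DIM < 100) and late
#' (DIM >= 100) lactation. The half-open convention maps every DIM to exactly
#' one stage while keeping the conventional 50/100-day cut points.
#'
#' @param dim integer vector of days in milk, all >= 1.
#' @return factor with ordered levels `early < mid < late`.
#' @export
assign_stage <- function(dim) {
  if (any(is.na(dim)) || any(dim < 1)) stop("dim must be >= 1")
  stage <- ifelse(dim < 50, "early", ifelse(dim < 100, "mid", "late"))
  factor(stage, levels = c("early", "mid", "late"), ordered = TRUE)
}

#' Parity class from parity number
#'
#' First-lactation cows are primiparous; all later lactations are multiparous.
#'
#' @param parity positive integer vector (number of calvings).
#' @return character vector `"primiparous"` / `"multiparous"`.
#' @export
parity_class <- function(parity) {
  if (any(parity < 1)) stop("parity must be >= 1")
  ifelse(parity == 1, "primiparous", "multiparous")
}

#' Read per-sample metadata
#'
#' CSV with header `sample_id, cow_id, parity, dim, sampling_event`. Derived
#' columns `parity_class` and `stage` are added. Each cow may contribute at
#' most one sample per sampling event.
#'
#' @param path CSV file.
#' @return data.frame of validated metadata.
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_metadata(md)
}

validate_metadata <- function(md) {
  need <- c("sample_id", "cow_id", "parity", "dim", "sampling_event")
  missing <- setdiff(need, names(md))
  if (length(missing)) stop("metadata lacks columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(md$sample_id)) stop("duplicate sample_id in metadata")
  if (!all(md$sampling_event %in% c(1L, 2L))) stop("sampling_event must be 1 or 2")
  if (anyDuplicated(md[, c("cow_id", "sampling_event")]))
    stop("a cow has more than one sample per sampling event")
  md$parity_class <- parity_class(md$parity)
  md$stage <- assign_stage(md$dim)
  md
}

#' Read a phenotype table
#'
#' CSV keyed by `sample_id` with columns `milk_yield, ecm, fat_pct,
#' protein_pct, methane` (kg/day, kg/day, %, %, g/day). Percentages must lie
#' in 0-100 and yields/methane must be non-negative.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "milk_yield", "ecm", "fat_pct", "protein_pct", "methane")
  missing <- setdiff(need, names(ph))
  if (length(missing)) stop("phenotype table lacks columns: ", paste(missing, collapse = ", "))
  pct <- c(ph$fat_pct, ph$protein_pct)
  if (any(pct < 0 | pct > 100, na.rm = TRUE)) stop("percentages must lie in [0, 100]")
  if (any(c(ph$milk_yield, ph$ecm, ph$methane) < 0, na.rm = TRUE))
    stop("yields and methane must be non-negative")
  ph
}

#' Derive an SCFA profile from concentrations
#'
#' Given per-sample short-chain fatty-acid concentrations (mmol/kg wet
#' sample), computes the total, molar proportions (%) and the
#' acetate:propionate ratio. The A:P ratio is `NA` (flagged undefined) where
#' propionate is zero.
#'
#' @param scfa data.frame with `sample_id` and acid concentration columns;
#'   must include `acetate` and `propionate`.
#' @return data.frame with the input concentrations plus `total`,
#'   `prop_<acid>` percentage columns, and `ap_ratio`.
#' @export
scfa_derive <- function(scfa) {
  need <- c("sample_id", "acetate", "propionate")
  missing <- setdiff(need, names(scfa))
  if (length(missing)) stop("SCFA table lacks columns: ", paste(missing, collapse = ", "))
  acids <- setdiff(names(scfa), "sample_id")
  conc <- as.matrix(scfa[, acids, drop = FALSE])
  if (any(conc < 0)) stop("concentrations must be non-negative")
  total <- rowSums(conc)
  if (any(total <= 0)) stop("all-zero SCFA profile in sample(s): ",
                            paste(scfa$sample_id[total <= 0], collapse = ", "))
  props <- 100 * conc / total
  colnames(props) <- paste0("prop_", acids)
  ap <- ifelse(scfa$propionate > 0, scfa$acetate / scfa$propionate, NA_real_)
  cbind(scfa, total = total, as.data.frame(props), ap_ratio = ap)
}

#' Read an SCFA concentration table
#'
#' @param path CSV keyed by `sample_id` with acid concentration columns
#'   (mmol/kg wet sample).
#' @return data.frame with derived totals, proportions and A:P ratio, per
#'   [scfa_derive()].
#' @export
read_scfa <- function(path) {
  scfa_derive(utils::read.csv(path, stringsAsFactors = FALSE))
}
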