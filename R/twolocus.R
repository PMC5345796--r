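# Two-locus penetrance model representation: balanced sample penetrance,
# discretization to fully-penetrant (binary) models, and canonical
# classification under the locus-swap / allele-flip symmetry group.

#' Balanced sample penetrance of a pair table
#'
#' Standardizes the per-cell penetrance using within-class genotype
#' proportions, `P_v = p1v / (p1v + p0v)` with `p_iv` the proportional
#' frequency of cell `v` among phenotype class `i`, making the values
#' comparable across datasets with different case:control ratios. 0.5
#' means no association in that cell.
#'
#' @param table a `pair_table`.
#' @return list with `values` (3x3, `NA` where unoccupied), `occupied`
#'   (3x3 logical), `p_case`, `p_control` (3x3 within-class proportions);
#'   class `balanced_penetrance`.
#' @export
balanced_penetrance <- function(table) {
  stopifnot(table$n_cases > 0, table$n_controls > 0)
  p1 <- table$counts["case", ] / table$n_cases
  p0 <- table$counts["control", ] / table$n_controls
  occ <- p1 + p0 > 0
  vals <- ifelse(occ, p1 / (p1 + p0), NA_real_)
  shape <- function(x) matrix(x, 3, 3, byrow = TRUE,
                              dimnames = list(gA = 0:2, gB = 0:2))
  structure(list(values = shape(vals), occupied = shape(occ),
                 p_case = shape(p1), p_control = shape(p0)),
            class = "balanced_penetrance")
}

#' Discretize a balanced penetrance table to a fully-penetrant model
#'
#' Cells with within-class frequency below `rare_freq` in BOTH cases and
#' controls are forced low risk; every other cell is high risk iff its
#' balanced penetrance exceeds 0.5 (the no-association boundary of the
#' balanced scale).
#'
#' @param bp a [balanced_penetrance()].
#' @param rare_freq rare-cell frequency heuristic (default 1%).
#' @return A `full_penetrance_model`: list with binary `cells` (3x3),
#'   integer `code` (0..511) and `class_id` (canonical orbit minimum,
#'   without risk-status complementation).
#' @export
discretize <- function(bp, rare_freq = 0.01) {
  rare <- bp$p_case < rare_freq & bp$p_control < rare_freq
  high <- !rare & !is.na(bp$values) & bp$values > 0.5
  cells <- matrix(as.integer(high), 3, 3)
  full_penetrance_model(cells)
}

#' Fully-penetrant two-locus model
#'
#' @param cells 3x3 binary matrix (rows = genotype at locus A, 0,1,2;
#'   columns = locus B), 1 = high risk.
#' @param label optional named-model tag (treated as opaque).
#' @return A `full_penetrance_model` with its row-major integer `code`
#'   (cell (0,0) is the most significant bit) and canonical `class_id`.
#' @export
full_penetrance_model <- function(cells, label = NULL) {
  cells <- matrix(as.integer(cells), 3, 3)
  stopifnot(all(cells %in% 0:1))
  structure(list(cells = cells, code = model_code(cells),
                 class_id = canonical_class(cells), label = label),
            class = "full_penetrance_model")
}

#' @rdname full_penetrance_model
#' @export
model_code <- function(cells) {
  bits <- as.integer(t(cells))          # row-major: (0,0),(0,1),...,(2,2)
  sum(bits * 2^(8:0))
}

code_to_cells <- function(code) {
  stopifnot(code >= 0, code <= 511)
  bits <- as.integer(intToBits(code))[9:1]
  matrix(bits, 3, 3, byrow = TRUE)
}

# symmetry group: locus swap (transpose), allele flip at A (row
# reversal), allele flip at B (column reversal); order 8. With
# complementation (swapping high/low risk status) the order is 16.
orbit_codes <- function(cells, include_complement = FALSE) {
  base <- list(cells, cells[3:1, ], cells[, 3:1], cells[3:1, 3:1])
  base <- c(base, lapply(base, t))
  if (include_complement) base <- c(base, lapply(base, function(m) 1L - m))
  vapply(base, model_code, numeric(1))
}

#' Canonical class of a fully-penetrant model
#'
#' Minimum code over the orbit of the model under the group generated by
#' locus swap, allele flip at each locus and (optionally) high/low risk
#' complementation. Without complementation protective and deleterious
#' patterns stay distinct, giving 100 non-constant classes; with it there
#' are 50.
#'
#' @param model a `full_penetrance_model`, 3x3 binary matrix, or integer
#'   code 0..511.
#' @param include_complement also identify complementary models
#'   (default `FALSE`).
#' @return integer class id (the orbit's minimum code).
#' @export
canonical_class <- function(model, include_complement = FALSE) {
  cells <- if (inherits(model, "full_penetrance_model")) model$cells
           else if (is.matrix(model)) matrix(as.integer(model), 3, 3)
           else code_to_cells(model)
  min(orbit_codes(cells, include_complement))
}

#' Count canonical model classes by exhaustive enumeration
#'
#' Enumerates all 512 binary 3x3 tables and counts distinct orbits.
#'
#' @param include_complement identify complementary models.
#' @param exclude_constant drop the constant all-low/all-high tables
#'   (two singleton orbits without complementation; one merged class
#'   with it).
#' @return integer class count.
#' @export
count_model_classes <- function(include_complement = FALSE,
                                exclude_constant = TRUE) {
  ids <- vapply(0:511, function(code)
    canonical_class(code, include_complement), numeric(1))
  classes <- unique(ids)
  if (exclude_constant) {
    drop <- unique(c(canonical_class(0, include_complement),
                     canonical_class(511, include_complement)))
    classes <- setdiff(classes, drop)
  }
  length(classes)
}

#' Model-class distribution over increasingly deep significance ranks
#'
#' For each `k` in `k_grid`, the fraction of the `k` most significant
#' models falling in each canonical class.
#'
#' @param class_ids class ids ordered by decreasing significance.
#' @param k_grid depths to evaluate (default: 10 log-spaced depths).
#' @return data frame with columns `k`, `class_id`, `fraction`; fractions
#'   sum to 1 at each `k`.
#' @export
class_distribution <- function(class_ids, k_grid = NULL) {
  n <- length(class_ids)
  if (n == 0) stop("no models")
  if (is.null(k_grid))
    k_grid <- unique(pmax(1, round(exp(seq(log(10), log(n), length.out = 10)))))
  k_grid <- k_grid[k_grid <= n]
  out <- do.call(rbind, lapply(k_grid, function(k) {
    tab <- table(class_ids[seq_len(k)])
    data.frame(k = k, class_id = as.numeric(names(tab)),
               fraction = as.numeric(tab) / k)
  }))
  rownames(out) <- NULL
  out
}
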