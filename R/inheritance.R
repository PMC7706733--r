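INHERITANCE_MODES <- c("conserved", "additive", "pied_dominant",
                       "collared_dominant", "overdominant", "underdominant")

#' Classify the mode of expression inheritance from hybrid fold changes
#'
#' Places each gene in the (x, y) plane of shrunken log2 fold changes,
#' x = LFC(hybrid/parentA "collared"), y = LFC(hybrid/parentB "pied"), and
#' assigns one of six modes using a fold-change threshold t =
#' log2(fold_threshold):
#' \itemize{
#'   \item both |x| and |y| below t: `conserved`;
#'   \item |x| below t, |y| at or beyond t: `collared_dominant` (hybrid
#'     tracks parentA);
#'   \item |x| at or beyond t, |y| below t: `pied_dominant`;
#'   \item both at or beyond t, same sign: `overdominant` (positive) or
#'     `underdominant` (negative);
#'   \item both at or beyond t, opposite signs: `additive` (hybrid
#'     intermediate, the y = -x diagonal).
#' }
#' Boundary values (|LFC| exactly t) count as beyond the threshold. The six
#' regions partition the plane, so every finite pair gets exactly one mode;
#' non-finite inputs return `NA`.
#'
#' @param x,y shrunken log2 fold changes (hybrid vs parentA, hybrid vs
#'   parentB).
#' @param fold_threshold fold-change threshold (> 1; default 1.125).
#' @return Factor of modes with levels `conserved`, `additive`,
#'   `pied_dominant`, `collared_dominant`, `overdominant`, `underdominant`.
#' @examples
#' classify_inheritance(c(0, -0.5, 0.5), c(0, 0.5, 0.5))
#' @export
classify_inheritance <- function(x, y, fold_threshold = 1.125) {
  if (!is.numeric(fold_threshold) || fold_threshold <= 1)
    stopf("'fold_threshold' must be > 1")
  t <- log2(fold_threshold)
  ax <- abs(x) >= t; ay <- abs(y) >= t
  mode <- rep(NA_character_, length(x))
  fin <- is.finite(x) & is.finite(y)
  mode[fin & !ax & !ay] <- "conserved"
  mode[fin & !ax & ay] <- "collared_dominant"
  mode[fin & ax & !ay] <- "pied_dominant"
  mode[fin & ax & ay & x > 0 & y > 0] <- "overdominant"
  mode[fin & ax & ay & x < 0 & y < 0] <- "underdominant"
  mode[fin & ax & ay & sign(x) != sign(y)] <- "additive"
  factor(mode, levels = INHERITANCE_MODES)
}

#' Major-axis (type II) regression
#'
#' Line through the centroid along the first eigenvector of the 2x2
#' covariance matrix of (x, y); the symmetric regression used to describe
#' the major variation of a bivariate cloud when neither variable is the
#' predictor.
#'
#' @param x,y numeric vectors (>= 3 finite pairs).
#' @return List `slope`, `intercept`, `centroid`, `eigenvalues`.
#' @export
type2_regression <- function(x, y) {
  fin <- is.finite(x) & is.finite(y)
  x <- x[fin]; y <- y[fin]
  if (length(x) < 3) stopf("type II regression needs >= 3 finite points")
  cv <- cov(cbind(x, y))
  if (sum(diag(cv)) <= 0) stopf("zero total variance")
  eg <- eigen(cv, symmetric = TRUE)
  v <- eg$vectors[, 1]
  slope <- if (abs(v[1]) < 1e-15) Inf else v[2] / v[1]
  centroid <- c(x = mean(x), y = mean(y))
  intercept <- if (is.finite(slope)) centroid[2] - slope * centroid[1] else NA_real_
  list(slope = unname(slope), intercept = unname(intercept),
       centroid = centroid, eigenvalues = eg$values)
}

#' Misexpression calls from the three pairwise contrasts
#'
#' A gene is eligible if its expression is conserved between the parental
#' species (CP status `nDE`), and misexpressed if, in addition, it is DE in
#' both hybrid-parent contrasts (HC and HP) with sign-consistent fold
#' changes - i.e. the hybrid lies above or below both parents, matching the
#' over-/underdominant definition of misexpression. Sign consistency can be
#' switched off to call misexpression from HC and HP significance alone.
#' Genes untested in any contrast are excluded (and counted in a message).
#'
#' @param de_cp,de_hc,de_hp `DEResult` data.frames from [run_de()] for the
#'   same tissue and gene universe (must include `shrunkenLfc`).
#' @param require_sign_consistency require sign(LFC HC) == sign(LFC HP)
#'   (default TRUE).
#' @return data.frame: `gene`, `x` (shrunken LFC HC), `y` (shrunken LFC
#'   HP), `eligible`, `misexpressed`, `direction` in `{over, under, none}`.
#' @export
call_misexpression <- function(de_cp, de_hc, de_hp,
                               require_sign_consistency = TRUE) {
  if (!identical(de_cp$gene, de_hc$gene) ||
      !identical(de_cp$gene, de_hp$gene))
    stopf("the three contrasts must share one gene universe")
  tested <- de_cp$status != "untested" & de_hc$status != "untested" &
    de_hp$status != "untested"
  if (any(!tested))
    message(sum(!tested), " gene(s) untested in >= 1 contrast excluded")
  g <- de_cp$gene[tested]
  eligible <- de_cp$status[tested] == "nDE"
  hc_de <- de_hc$status[tested] == "DE"
  hp_de <- de_hp$status[tested] == "DE"
  sgn_ok <- sign(de_hc$shrunkenLfc[tested]) == sign(de_hp$shrunkenLfc[tested])
  mis <- eligible & hc_de & hp_de & (!require_sign_consistency | sgn_ok)
  both_up <- de_hc$shrunkenLfc[tested] > 0 & de_hp$shrunkenLfc[tested] > 0
  direction <- ifelse(!mis, "none", ifelse(both_up, "over", "under"))
  data.frame(gene = g,
             x = de_hc$shrunkenLfc[tested], y = de_hp$shrunkenLfc[tested],
             eligible = eligible, misexpressed = mis, direction = direction,
             stringsAsFactors = FALSE)
}

#' Inheritance-mode frequencies by chromosome class
#'
#' @param calls data.frame with columns `gene`, `tissue`, `mode` (from
#'   [classify_inheritance()]; `NA` modes are dropped).
#' @param chrom_class named character vector: chromosome class per gene
#'   (every called gene must have one).
#' @return data.frame `tissue`, `chrom_class`, `mode`, `n`, `frequency`;
#'   frequencies sum to 1 within each (tissue, class).
#' @export
inheritance_frequencies <- function(calls, chrom_class) {
  if (!all(calls$gene %in% names(chrom_class)))
    stopf("every called gene needs a chromosome class")
  ok <- !is.na(calls$mode)
  calls <- calls[ok, ]
  cls <- chrom_class[calls$gene]
  tab <- as.data.frame(table(tissue = calls$tissue, chrom_class = cls,
                             mode = factor(calls$mode,
                                           levels = INHERITANCE_MODES)),
                       stringsAsFactors = FALSE)
  names(tab)[4] <- "n"
  tot <- aggregate(n ~ tissue + chrom_class, tab, sum)
  names(tot)[3] <- "total"
  tab <- merge(tab, tot, by = c("tissue", "chrom_class"))
  tab$frequency <- ifelse(tab$total > 0, tab$n / tab$total, NA_real_)
  tab$total <- NULL
  tab[order(tab$tissue, tab$chrom_class, match(tab$mode, INHERITANCE_MODES)), ]
}
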