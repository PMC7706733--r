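#' Pipeline configuration
#'
#' Collects input/output paths and analysis settings. The defaults are the
#' study-standard ones: FDR threshold 0.05, inheritance fold-change
#' threshold 1.125, 99 Monte-Carlo permutations, SNP filters of minimum
#' coverage 10 and minimum allelic depth greater than 2 with at least two
#' phased SNPs per gene.
#'
#' @param counts,samples paths to the count matrix and sample table TSVs.
#' @param allele_counts optional path to the phased allelic count TSV;
#'   `NULL` skips the ASE and inference-on-ASE stages.
#' @param annotation optional path to the gene annotation TSV; `NULL` skips
#'   TPM, fast-Z, and determinant stages.
#' @param out_dir output directory (created if absent).
#' @param fold_threshold inheritance classification threshold (> 1).
#' @param alpha FDR threshold for DE and ASE significance.
#' @param n_perm Monte-Carlo permutations for between-groups PCA.
#' @param min_coverage,min_allelic_depth,min_snps ASE SNP filters.
#' @param require_sign_consistency misexpression needs sign-consistent HC
#'   and HP fold changes (default TRUE).
#' @param tau_transform `"log2p1"` or `"none"` for the tau index.
#' @param pseudo_reference passed to [size_factors()].
#' @param seed seed for the pipeline's stochastic stages (permutations).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, samples, allele_counts = NULL,
                            annotation = NULL, out_dir = "hybridexpr_out",
                            fold_threshold = 1.125, alpha = 0.05,
                            n_perm = 99, min_coverage = 10,
                            min_allelic_depth = 2, min_snps = 2,
                            require_sign_consistency = TRUE,
                            tau_transform = "log2p1",
                            pseudo_reference = FALSE, seed = 1L) {
  if (fold_threshold <= 1) stopf("'fold_threshold' must be > 1")
  assert_prob(alpha, "alpha")
  n_perm <- assert_count(n_perm, "n_perm")
  structure(list(counts = counts, samples = samples,
                 allele_counts = allele_counts, annotation = annotation,
                 out_dir = out_dir, fold_threshold = fold_threshold,
                 alpha = alpha, n_perm = n_perm,
                 min_coverage = min_coverage,
                 min_allelic_depth = min_allelic_depth,
                 min_snps = min_snps,
                 require_sign_consistency = require_sign_consistency,
                 tau_transform = tau_transform,
                 pseudo_reference = pseudo_reference,
                 seed = assert_count(seed, "seed", 0L)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with keys matching [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

pipeline_log <- function(state, fmt, ...) {
  line <- sprintf(fmt, ...)
  cat(line, "\n", sep = "", file = state$log, append = TRUE)
  invisible(line)
}

#' Run the full analysis pipeline
#'
#' Executes, per tissue, the stages in order: differential expression for
#' the three contrasts (CP, HC, HP), expression structure (TPM, census,
#' tau, PCA with hybrid projection, between-groups PCA), inheritance-mode
#' classification and misexpression calling, allele-specific expression,
#' and the regulatory-inference battery. All outputs are TSV/JSON files
#' under `out_dir`; a run manifest records the config hash and seed, so a
#' rerun with identical inputs and config is bit-identical for the
#' deterministic stages (permutation p-values are seeded from the config).
#'
#' @param config a [pipeline_config()].
#' @param stages subset of `c("de", "structure", "inherit", "ase",
#'   "infer")` to execute; later stages read earlier stages' outputs from
#'   `out_dir` when not run in the same call.
#' @return Invisibly, a list with the in-memory results and output paths.
#' @export
run_pipeline <- function(config,
                         stages = c("de", "structure", "inherit", "ase",
                                    "infer")) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- list(log = file.path(config$out_dir, "run.log"))
  cat("", file = state$log)
  res <- list()
  run_stage <- function(name, fun) {
    pipeline_log(state, "stage %s: start", name)
    out <- tryCatch(fun(), error = function(e) {
      pipeline_log(state, "stage %s: FAILED: %s", name, conditionMessage(e))
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    pipeline_log(state, "stage %s: done", name)
    out
  }

  counts <- read_counts(config$counts)
  samples <- read_samples(config$samples)
  validate_inputs(counts, samples)
  annotation <- if (!is.null(config$annotation))
    read_annotation(config$annotation) else NULL
  tissues <- unique(samples$tissue)
  od <- config$out_dir
  de_path <- function(tt, cc) file.path(od, sprintf("de_%s_%s.tsv", tt, cc))

  load_de <- function(tt, cc) {
    p <- de_path(tt, cc)
    if (!file.exists(p))
      stopf("missing input %s: run the 'de' stage first", p)
    d <- read.delim(p, stringsAsFactors = FALSE)
    d
  }

  if ("de" %in% stages) {
    res$de <- run_stage("de", function() {
      out <- list()
      for (tt in tissues) {
        out[[tt]] <- de_contrasts(counts, samples, tt, alpha = config$alpha,
                                  pseudo_reference = config$pseudo_reference)
        for (cc in names(out[[tt]]))
          write_tsv(out[[tt]][[cc]], de_path(tt, cc))
      }
      out
    })
  }
  get_de <- function(tt, cc) {
    if (!is.null(res$de)) res$de[[tt]][[cc]] else load_de(tt, cc)
  }

  if ("structure" %in% stages) {
    res$structure <- run_stage("structure", function() {
      out <- list()
      lt <- rlog_like(counts, size_factors(counts,
                                           config$pseudo_reference))
      if (!is.null(annotation)) {
        len <- setNames(annotation$length, annotation$gene)[rownames(counts)]
        tp <- tpm(counts, len)
        out$census <- expressed_census(tp, samples)
        write_tsv(out$census, file.path(od, "expressed_census.tsv"))
        out$tau <- tau_by_species(tp, samples,
                                  transform = config$tau_transform)
        write_tsv(out$tau, file.path(od, "tau.tsv"))
      }
      ## within-tissue PCA of parents with hybrids projected on top
      out$pca <- list()
      for (tt in tissues) {
        sub <- samples[samples$tissue == tt, ]
        par <- sub$sample[sub$species != "hybrid"]
        hyb <- sub$sample[sub$species == "hybrid"]
        if (length(par) < 2) next
        mod <- pca_expression(lt[, par, drop = FALSE])
        sc <- mod$scores
        if (length(hyb))
          sc <- rbind(sc, project_samples(mod, lt[, hyb, drop = FALSE]))
        out$pca[[tt]] <- list(model = mod, scores = sc)
        write_tsv(data.frame(sample = rownames(sc), sc[, 1:2, drop = FALSE]),
                  file.path(od, sprintf("pca_scores_%s.tsv", tt)))
      }
      ## between-groups PCA: tissue, then species conditioned on tissue
      if (length(tissues) >= 2) {
        bg_t <- between_group_pca(lt, samples$tissue, config$n_perm,
                                  seed = stream_seed(config$seed, "bg_tissue"))
        bg_s <- between_group_pca(lt, samples$species, config$n_perm,
                                  condition_on = samples$tissue,
                                  seed = stream_seed(config$seed, "bg_species"))
        out$bgpca <- list(tissue = bg_t, species_given_tissue = bg_s)
        jsonlite::write_json(
          list(tissue = list(inertia = bg_t$inertia, p = bg_t$p,
                             n_perm = bg_t$n_perm),
               species_given_tissue = list(inertia = bg_s$inertia,
                                           p = bg_s$p, n_perm = bg_s$n_perm)),
          file.path(od, "bgpca.json"), auto_unbox = TRUE, digits = NA)
      }
      out
    })
  }

  if ("inherit" %in% stages) {
    res$inherit <- run_stage("inherit", function() {
      out <- list(calls = list(), misexpression = list(), type2 = list())
      for (tt in tissues) {
        hc <- get_de(tt, "HC"); hp <- get_de(tt, "HP")
        cp <- get_de(tt, "CP")
        mode <- classify_inheritance(hc$shrunkenLfc, hp$shrunkenLfc,
                                     config$fold_threshold)
        calls <- data.frame(gene = hc$gene, tissue = tt,
                            x = hc$shrunkenLfc, y = hp$shrunkenLfc,
                            mode = as.character(mode),
                            stringsAsFactors = FALSE)
        out$calls[[tt]] <- calls
        out$type2[[tt]] <- type2_regression(calls$x, calls$y)
        mis <- call_misexpression(cp, hc, hp,
                                  config$require_sign_consistency)
        mis$tissue <- tt
        out$misexpression[[tt]] <- mis
        write_tsv(merge(calls, mis[, c("gene", "eligible", "misexpressed",
                                       "direction")],
                        by = "gene", all.x = TRUE),
                  file.path(od, sprintf("inheritance_%s.tsv", tt)))
      }
      if (!is.null(annotation)) {
        cls <- setNames(annotation$chrom_class, annotation$gene)
        allcalls <- do.call(rbind, out$calls)
        out$frequencies <- inheritance_frequencies(allcalls, cls)
        write_tsv(out$frequencies,
                  file.path(od, "inheritance_frequencies.tsv"))
      }
      out
    })
  }

  if ("ase" %in% stages && !is.null(config$allele_counts)) {
    res$ase <- run_stage("ase", function() {
      ac <- read_allele_counts(config$allele_counts)
      sp_of <- unique(samples[, c("individual", "species")])
      ac$species <- sp_of$species[match(ac$individual, sp_of$individual)]
      if (anyNA(ac$species))
        stopf("individual(s) absent from the sample table: %s",
              paste(unique(ac$individual[is.na(ac$species)]), collapse = ", "))
      out <- list()
      for (sp in unique(ac$species)) {
        out[[sp]] <- run_ase(ac[ac$species == sp, ],
                             min_coverage = config$min_coverage,
                             min_allelic_depth = config$min_allelic_depth,
                             min_snps = config$min_snps,
                             alpha = config$alpha)
      }
      ind <- do.call(rbind, lapply(names(out), function(sp)
        cbind(species = sp, out[[sp]]$individual)))
      pop <- do.call(rbind, lapply(names(out), function(sp)
        cbind(species = sp, out[[sp]]$population)))
      write_tsv(ind, file.path(od, "ase_individual.tsv"))
      write_tsv(pop, file.path(od, "ase_population.tsv"))
      out
    })
  }

  if ("infer" %in% stages) {
    res$infer <- run_stage("infer", function() {
      pop <- if (!is.null(res$ase)) {
        do.call(rbind, lapply(names(res$ase), function(sp)
          cbind(species = sp, res$ase[[sp]]$population)))
      } else if (!is.null(config$allele_counts)) {
        p <- file.path(od, "ase_population.tsv")
        if (!file.exists(p))
          stopf("missing input %s: run the 'ase' stage first", p)
        read.delim(p, stringsAsFactors = FALSE)
      } else NULL
      if (is.null(annotation))
        stopf("the inference stage needs a gene annotation table")
      cls <- setNames(annotation$chrom_class, annotation$gene)
      rows <- list(); determinants <- list()
      cp_by_tissue <- setNames(lapply(tissues, get_de, cc = "CP"), tissues)
      fz <- fast_z_test(cp_by_tissue, cls)
      rows[[length(rows) + 1]] <- data.frame(
        test = "fast_z", tissue = fz$tissue, statistic = NA_real_,
        p = fz$p, p_holm = fz$p_holm, direction = NA_real_,
        n1 = fz$de_z + fz$nde_z, n0 = fz$de_a + fz$nde_a,
        stringsAsFactors = FALSE)
      for (tt in tissues) {
        cp <- cp_by_tissue[[tt]]
        ## CNE fixed-difference association with expression divergence
        if (any(!is.na(annotation$cne_flag))) {
          auto <- cp$status != "untested" & cls[cp$gene] %in% "autosome"
          fl <- setNames(annotation$cne_flag, annotation$gene)[cp$gene[auto]]
          a <- mwu_association(abs(cp$shrunkenLfc[auto]), fl)
          rows[[length(rows) + 1]] <- data.frame(
            test = "cne_divergence", tissue = tt, statistic = a$U,
            p = a$p, p_holm = NA_real_, direction = a$direction,
            n1 = a$n1, n0 = a$n0, stringsAsFactors = FALSE)
        }
        if (!is.null(pop)) {
          byspecies <- split(pop[pop$tissue == tt, ], pop$species[pop$tissue == tt])
          src_names <- c(hybrid = "hybrid", parentA = "parentA",
                         parentB = "parentB")
          byspecies <- byspecies[intersect(names(src_names), names(byspecies))]
          if (length(byspecies)) {
            ad <- ase_de_association(cp, byspecies, cls)
            rows[[length(rows) + 1]] <- data.frame(
              test = paste0("ase_de_", ad$source), tissue = tt,
              statistic = ad$U, p = ad$p, p_holm = NA_real_,
              direction = ad$direction, n1 = ad$n_ase, n0 = ad$n_non,
              stringsAsFactors = FALSE)
          }
          hyb_pop <- byspecies[["hybrid"]]
          mis <- if (!is.null(res$inherit))
            res$inherit$misexpression[[tt]]
          else {
            hc <- get_de(tt, "HC"); hp <- get_de(tt, "HP")
            call_misexpression(cp, hc, hp, config$require_sign_consistency)
          }
          if (!is.null(hyb_pop) && nrow(hyb_pop)) {
            ct <- compensation_test(mis, hyb_pop, cls)
            rows[[length(rows) + 1]] <- data.frame(
              test = "compensation", tissue = tt, statistic = ct$statistic,
              p = ct$p, p_holm = NA_real_, direction = NA_real_,
              n1 = sum(ct$table[1, ]), n0 = sum(ct$table[2, ]),
              stringsAsFactors = FALSE)
          }
        }
        if (all(c("ppi", "tau", "phi", "piNpiS", "dNdS", "fst") %in%
                names(annotation)) && !anyNA(annotation$tau)) {
          determinants[[tt]] <- tryCatch(
            cbind(tissue = tt,
                  glm_determinants(cp, annotation, mode = "binomial")),
            error = function(e) NULL)
        }
      }
      assoc <- do.call(rbind, rows)
      write_tsv(assoc, file.path(od, "associations.tsv"))
      det <- do.call(rbind, determinants)
      if (!is.null(det)) write_tsv(det, file.path(od, "determinants.tsv"))
      list(associations = assoc, determinants = det)
    })
  }

  manifest <- list(
    package = "hybridexpr",
    config = unclass(config),
    config_hash = fnv1a(paste(deparse(unclass(config)), collapse = "")),
    seed = config$seed,
    stages = stages,
    outputs = sort(setdiff(list.files(od, pattern = "\\.(tsv|json)$"),
                           "manifest.json")))
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(res)
}
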