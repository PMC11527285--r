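#' Specification of a synthetic planted-module expression study
#'
#' Emulates the structure of a case/control single-cell cohort with matched
#' bulk cohorts: log-scale Gaussian baseline expression, disjoint gene
#' modules that are either cell-type markers or disease modules (shifted by
#' `disease_effect` in case subjects, within the affected cell types),
#' zero-inflation (dropout) for single-cell measurements, and per-cohort
#' affine platform shifts for bulk data.
#'
#' The default design: 600 genes, 3 cell types, six disjoint 30-gene modules
#' (three cell-type markers, effect +1.5; three disease modules with effect
#' +1.0 affecting all types / type 1 / types 2-3), baseline N(1, 0.5) on the
#' log2 scale clipped at 0, 30% dropout, 40 case + 40 control subjects with
#' 50 cells each.
#'
#' @param n_genes number of genes.
#' @param n_cell_types number of cell types.
#' @param module_size genes per planted module.
#' @param marker_effect additive log-scale shift of a cell type's marker
#'   module in that type.
#' @param disease_effect additive shift (delta) of disease modules in case
#'   subjects' affected cells.
#' @param baseline_mean,baseline_sd log-scale Gaussian baseline.
#' @param subject_effect_sd sd of a per-subject latent activity factor added
#'   to disease-module genes (within affected cell types) in all of a
#'   subject's cells, for cases and controls alike. This models
#'   between-subject heterogeneity of inflammation state, which keeps the
#'   planted classification task in a realistic (non-saturated) performance
#'   regime. Default 0.35.
#' @param dropout_rate probability an entry is zeroed in single-cell output.
#' @param n_subjects_case,n_subjects_control subjects per arm.
#' @param cells_per_subject cells simulated per subject.
#' @param bulk_platform_shift list with `scale`, `offset`, `noise_sd` and the
#'   per-gene heterogeneity of the platform map: `gene_scale_sd` (sd of the
#'   lognormal per-gene scale factor) and `gene_offset_sd` (sd of the
#'   Gaussian per-gene offset).
#' @param bulk_composition_alpha Dirichlet concentration of per-subject
#'   cell-type proportions in bulk cohorts (default 2; single-cell data uses
#'   uniform cell-type assignment). Low values emulate the strong
#'   between-subject composition variation of real bulk samples, which is a
#'   major part of the single-cell to bulk domain gap.
#' @param seed RNG seed; the same spec and seed reproduce the data exactly.
#' @param modules optional explicit module list (each element:
#'   `list(name, genes, kind = "marker"/"disease", cell_type, effect,
#'   affected_types)`); defaults are built as described above.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_genes = 600, n_cell_types = 3, module_size = 30,
                           marker_effect = 1.5, disease_effect = 1.0,
                           baseline_mean = 1.0, baseline_sd = 0.5,
                           subject_effect_sd = 0.35,
                           dropout_rate = 0.3, n_subjects_case = 40,
                           n_subjects_control = 40, cells_per_subject = 50,
                           bulk_platform_shift = list(scale = 1, offset = 0,
                                                      noise_sd = 0.3,
                                                      gene_scale_sd = 0.3,
                                                      gene_offset_sd = 1.0),
                           bulk_composition_alpha = 2,
                           seed = 1, modules = NULL) {
  stopifnot(n_genes >= 1, n_cell_types >= 1, dropout_rate >= 0,
            dropout_rate < 1, cells_per_subject >= 1,
            n_subjects_case >= 1, n_subjects_control >= 1)
  if (is.null(modules)) {
    blocks <- split(seq_len(min(6 * module_size, n_genes)),
                    rep(seq_len(6), each = module_size,
                        length.out = min(6 * module_size, n_genes)))
    aff <- list(seq_len(n_cell_types), 1L,
                setdiff(seq_len(n_cell_types), 1L))
    modules <- c(
      lapply(seq_len(min(n_cell_types, 3L)), function(t)
        list(name = paste0("marker_type", t), genes = blocks[[t]],
             kind = "marker", cell_type = t, effect = marker_effect)),
      lapply(1:3, function(k)
        list(name = paste0("disease_", k), genes = blocks[[3L + k]],
             kind = "disease", effect = disease_effect,
             affected_types = aff[[k]])))
  }
  all_genes <- unlist(lapply(modules, `[[`, "genes"))
  if (anyDuplicated(all_genes)) stop("modules must be pairwise disjoint")
  if (any(all_genes > n_genes)) stop("module gene index exceeds n_genes")
  structure(list(n_genes = n_genes, n_cell_types = n_cell_types,
                 modules = modules, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd,
                 subject_effect_sd = subject_effect_sd,
                 dropout_rate = dropout_rate,
                 n_subjects_case = n_subjects_case,
                 n_subjects_control = n_subjects_control,
                 cells_per_subject = cells_per_subject,
                 bulk_platform_shift = bulk_platform_shift,
                 bulk_composition_alpha = bulk_composition_alpha,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# internal: simulate all cells of a subject set; returns pre-dropout values.
# composition_alpha = NULL assigns cell types uniformly; a numeric value
# draws per-subject type proportions from a symmetric Dirichlet
simulate_cells <- function(spec, subj_labels, composition_alpha = NULL) {
  n_subj <- length(subj_labels)
  n_cells <- n_subj * spec$cells_per_subject
  subj <- rep(seq_len(n_subj), each = spec$cells_per_subject)
  if (is.null(composition_alpha)) {
    ct <- sample.int(spec$n_cell_types, n_cells, replace = TRUE)
  } else {
    T_ <- spec$n_cell_types
    ct <- unlist(lapply(seq_len(n_subj), function(sj) {
      g <- stats::rgamma(T_, composition_alpha)
      sample.int(T_, spec$cells_per_subject, replace = TRUE, prob = g / sum(g))
    }))
  }
  vals <- matrix(stats::rnorm(spec$n_genes * n_cells, spec$baseline_mean,
                              spec$baseline_sd),
                 spec$n_genes, n_cells)
  case_cell <- subj_labels[subj] == 1L
  # latent per-subject severity factor, shared across disease modules
  sev <- stats::rnorm(n_subj, 0, spec$subject_effect_sd %||% 0)
  for (m in spec$modules) {
    if (m$kind == "marker") {
      sel <- ct == m$cell_type
      if (any(sel))
        vals[m$genes, sel] <- vals[m$genes, sel] + m$effect
    } else {
      sel <- ct %in% m$affected_types
      shift <- sev[subj] + m$effect * case_cell
      if (any(sel))
        vals[m$genes, sel] <- vals[m$genes, sel] +
          rep(shift[sel], each = length(m$genes))
    }
  }
  vals[vals < 0] <- 0
  list(values = vals, subject = subj, cell_type = ct)
}

# internal: gene-module membership table
module_table <- function(spec) {
  gene_ids <- sprintf("g%04d", seq_len(spec$n_genes))
  mod <- rep(NA_character_, spec$n_genes)
  kind <- rep("background", spec$n_genes)
  for (m in spec$modules) {
    mod[m$genes] <- m$name
    kind[m$genes] <- m$kind
  }
  data.frame(gene_id = gene_ids, module = mod, kind = kind,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic single-cell cohort
#'
#' Draws cells per subject, assigns cell types uniformly, plants marker and
#' disease modules, clips negative log-scale values at zero and applies
#' independent dropout. Deterministic given the spec's seed.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `dataset` (a `labelled_dataset`, platform
#'   `single_cell`), `truth` (cell table and gene-module table) and `spec`.
#' @export
generate_single_cell <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    labels_subj <- c(rep(1L, spec$n_subjects_case),
                     rep(0L, spec$n_subjects_control))
    sim <- simulate_cells(spec, labels_subj)
    vals <- sim$values
    drop_mask <- matrix(stats::runif(length(vals)) < spec$dropout_rate,
                        nrow(vals), ncol(vals))
    vals[drop_mask] <- 0
    gene_ids <- sprintf("g%04d", seq_len(spec$n_genes))
    cell_ids <- sprintf("cell_%05d", seq_len(ncol(vals)))
    subj_ids <- sprintf("subj_%03d", sim$subject)
    m <- expression_matrix(vals, gene_ids, cell_ids,
                           platform_tag = "single_cell",
                           normalization_tag = "synthetic_log2")
    ds <- labelled_dataset(m, labels_subj[sim$subject],
                           cell_type = paste0("type_", sim$cell_type),
                           subject_id = subj_ids)
    truth <- list(
      cells = data.frame(cell_id = cell_ids, subject_id = subj_ids,
                         label = labels_subj[sim$subject],
                         cell_type = sim$cell_type),
      genes = module_table(spec))
    list(dataset = ds, truth = truth, spec = spec)
  })
}

# internal: default per-cohort platform shifts, deterministic in n_cohorts
default_shifts <- function(spec, n_cohorts) {
  base <- spec$bulk_platform_shift
  scales <- base$scale * seq(0.7, 1.3, length.out = max(n_cohorts, 2))
  offsets <- base$offset + seq(0, 2, length.out = max(n_cohorts, 2))
  lapply(seq_len(n_cohorts), function(cst)
    list(scale = scales[cst], offset = offsets[cst],
         noise_sd = base$noise_sd,
         gene_scale_sd = base$gene_scale_sd %||% 0,
         gene_offset_sd = base$gene_offset_sd %||% 0))
}

#' Generate synthetic bulk cohorts
#'
#' Each cohort simulates fresh subjects from the same generative process;
#' a subject's profile is the mean of its cells' pre-dropout expression
#' (dropout is a single-cell measurement artifact). Every cohort then
#' applies its own platform map `a_g * x + b_g` plus Gaussian measurement
#' noise, where the per-gene factors `a_g` (lognormal around the cohort
#' scale) and `b_g` (Gaussian around the cohort offset) model probe-level
#' heterogeneity between platforms. Values are clipped at 0.
#'
#' @param spec a [synthetic_spec()].
#' @param n_cohorts number of cohorts (>= 1).
#' @param shifts optional list of per-cohort shift lists (`scale`, `offset`,
#'   `noise_sd`, `gene_scale_sd`, `gene_offset_sd`); defaults vary scale
#'   over 0.7-1.3 and offset over 0-2 across cohorts.
#' @return List of `labelled_dataset`s (platform `microarray`), named
#'   `cohort_1`, `cohort_2`, ...
#' @export
generate_bulk <- function(spec, n_cohorts = 3, shifts = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"), n_cohorts >= 1)
  if (spec$cells_per_subject < 1) stop("cells_per_subject must be >= 1")
  if (is.null(shifts)) shifts <- default_shifts(spec, n_cohorts)
  stopifnot(length(shifts) == n_cohorts)
  gene_ids <- sprintf("g%04d", seq_len(spec$n_genes))
  with_seed(spec$seed + 7919L, {
    lapply(seq_len(n_cohorts), function(cst) {
      sh <- shifts[[cst]]
      labels_subj <- c(rep(1L, spec$n_subjects_case),
                       rep(0L, spec$n_subjects_control))
      sim <- simulate_cells(spec, labels_subj,
                            composition_alpha = spec$bulk_composition_alpha)
      n_subj <- length(labels_subj)
      prof <- vapply(seq_len(n_subj), function(sj)
        rowMeans(sim$values[, sim$subject == sj, drop = FALSE]),
        numeric(spec$n_genes))
      a_g <- sh$scale * exp(stats::rnorm(spec$n_genes, 0,
                                         sh$gene_scale_sd %||% 0))
      b_g <- sh$offset + stats::rnorm(spec$n_genes, 0,
                                      sh$gene_offset_sd %||% 0)
      shifted <- prof * a_g + b_g +
        matrix(stats::rnorm(length(prof), 0, sh$noise_sd),
               nrow(prof), ncol(prof))
      shifted[shifted < 0] <- 0
      ids <- sprintf("c%d_subj_%03d", cst, seq_len(n_subj))
      m <- expression_matrix(shifted, gene_ids, ids,
                             platform_tag = "microarray",
                             normalization_tag = "synthetic_log2_shifted")
      labelled_dataset(m, labels_subj, subject_id = ids,
                       cohort_id = rep(paste0("cohort_", cst), n_subj))
    }) |> stats::setNames(paste0("cohort_", seq_len(n_cohorts)))
  })
}

#' Write the planted modules of a spec as a GMT collection
#'
#' Produces a toy gene-set collection from the spec's planted modules, so
#' enrichment analyses can run end-to-end on synthetic data.
#'
#' @param spec a [synthetic_spec()].
#' @param path output GMT path.
#' @return `path`, invisibly.
#' @export
write_module_gmt <- function(spec, path) {
  gene_ids <- sprintf("g%04d", seq_len(spec$n_genes))
  lines <- vapply(spec$modules, function(m)
    paste(c(m$name, paste0("planted_", m$kind, "_module"),
            gene_ids[m$genes]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Gene-set collection of a spec's planted modules
#' @param spec a [synthetic_spec()].
#' @return A `gene_set_collection` with one set per planted module.
#' @export
module_collection <- function(spec) {
  gene_ids <- sprintf("g%04d", seq_len(spec$n_genes))
  sets <- lapply(spec$modules, function(m) gene_ids[m$genes])
  names(sets) <- vapply(spec$modules, `[[`, "", "name")
  gene_set_collection(sets, source = "planted_modules")
}
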