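#' Simulation specification for multicohort expression data
#'
#' Describes a set of transcriptome cohorts with a shared gene namespace, a
#' small planted set of response-informative genes, and per-cohort
#' location/scale/shape distortions that emulate cross-platform differences.
#' The defaults emulate the study design this package targets: four cohorts
#' of 16 (8 NR / 8 R), 23, 38 and 299 patients with distinct distributional
#' signatures.
#'
#' @param cohort_sizes integer vector of per-cohort sample counts (all >= 4).
#' @param class_balance fraction of samples labelled R (responder) per cohort;
#'   scalar or one value per cohort, strictly between 0 and 1. Counts are
#'   rounded deterministically, so size 16 at balance 0.5 gives exactly
#'   8 NR / 8 R.
#' @param n_genes total number of genes.
#' @param n_informative number of genes carrying a true response effect.
#' @param effect_size standardized mean shift d between R and NR samples for
#'   informative genes (applied before cohort distortion), >= 0.
#' @param cohort_shift per-cohort additive location offset (recycled).
#' @param cohort_scale per-cohort multiplicative factor (> 0, recycled).
#' @param shape marginal distribution family: "gaussian", or "lognormal"
#'   (Gaussian core exponentiated after distortion, so rank structure is
#'   preserved while skew-removing scalers are exercised).
#' @param label_noise probability that an observed label is flipped relative
#'   to the latent response (default 0).
#' @param seed integer seed; identical spec + seed gives bit-identical data.
#' @return an object of class `cohort_sim_spec`.
#' @seealso [generate_cohorts()]
#' @export
cohort_sim_spec <- function(cohort_sizes = c(16L, 23L, 38L, 299L),
                            class_balance = 0.5,
                            n_genes = 500L,
                            n_informative = 10L,
                            effect_size = 2,
                            cohort_shift = c(0, 1, -1, 2),
                            cohort_scale = c(1, 2, 0.5, 1.5),
                            shape = c("gaussian", "lognormal"),
                            label_noise = 0,
                            seed = 1L) {
  shape <- match.arg(shape)
  if (any(cohort_sizes < 4L))
    stop_field("cohort_sizes", "all cohort sizes must be >= 4")
  if (any(class_balance <= 0) || any(class_balance >= 1))
    stop_field("class_balance", "must lie strictly between 0 and 1")
  if (n_informative > n_genes)
    stop_field("n_informative", "cannot exceed n_genes")
  if (effect_size < 0) stop_field("effect_size", "must be >= 0")
  if (any(cohort_scale <= 0)) stop_field("cohort_scale", "must be > 0")
  if (label_noise < 0 || label_noise >= 1)
    stop_field("label_noise", "must lie in [0, 1)")
  structure(list(
    cohort_sizes = as.integer(cohort_sizes),
    class_balance = rep_len(class_balance, length(cohort_sizes)),
    n_genes = as.integer(n_genes),
    n_informative = as.integer(n_informative),
    effect_size = effect_size,
    cohort_shift = rep_len(cohort_shift, length(cohort_sizes)),
    cohort_scale = rep_len(cohort_scale, length(cohort_sizes)),
    shape = shape,
    label_noise = label_noise,
    seed = as.integer(seed)
  ), class = "cohort_sim_spec")
}

#' Expression cohort container
#'
#' A genes x samples matrix with binary NR/R labels and a cohort identity;
#' the unit all transcriptome stages operate on.
#'
#' @param values numeric genes x samples matrix with gene row names and
#'   sample column names.
#' @param labels per-sample binary labels (NR = 0, R = 1); both classes must
#'   be present.
#' @param cohort_id cohort name.
#' @return an object of class `expression_cohort`.
#' @export
expression_cohort <- function(values, labels, cohort_id) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_field("values", "gene row names and sample column names are required")
  if (length(labels) != ncol(values))
    stop_field("labels", "length must equal the sample count")
  labels <- check_binary_labels(labels)
  structure(list(values = values,
                 labels = stats::setNames(labels, colnames(values)),
                 cohort_id = as.character(cohort_id)),
            class = "expression_cohort")
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat(sprintf("<expression_cohort '%s'> %d genes x %d samples (NR = %d, R = %d)\n",
              x$cohort_id, nrow(x$values), ncol(x$values),
              sum(x$labels == 0L), sum(x$labels == 1L)))
  invisible(x)
}

gene_ids <- function(n) sprintf("G%04d", seq_len(n))

# A few synthetic gene ids are aliased to familiar bladder-cancer symbols so
# documentation examples read naturally; the mapping claims no real biology.
#' Alias table mapping synthetic gene ids to familiar gene symbols
#'
#' Purely cosmetic mapping used in examples (GLS, KEAP1, FOXA1, ...); the
#' synthetic data carry no real biology.
#' @param n_genes number of genes in the simulated matrix.
#' @return data.frame with columns `gene_id`, `alias`.
#' @export
gene_alias_table <- function(n_genes = 500L) {
  symbols <- c("GLS", "KEAP1", "FOXA1", "IL15RA", "AFAP1", "TFEB", "CTNNB1",
               "MTCH1", "CBS", "GPX2")
  n <- min(length(symbols), n_genes)
  data.frame(gene_id = gene_ids(n_genes)[seq_len(n)],
             alias = symbols[seq_len(n)], stringsAsFactors = FALSE)
}

#' Generate synthetic multicohort expression data with known ground truth
#'
#' Draws independent Gaussian noise per gene, adds a standardized mean shift
#' `effect_size` to the informative genes in responder samples, then applies
#' per-cohort location/scale distortion (and exponentiation under the
#' lognormal shape). Class effects are applied before cohort distortion, so
#' within-cohort class separation on standardized data is unaffected by the
#' distortion.
#'
#' @param spec a [cohort_sim_spec()].
#' @return list with `cohorts` (list of [expression_cohort()]) and
#'   `ground_truth` (list with `informative_genes`, `latent_response`,
#'   `effect_size`).
#' @examples
#' sim <- generate_cohorts(cohort_sim_spec(cohort_sizes = 16, seed = 7))
#' table(sim$cohorts[[1]]$labels)
#' @export
generate_cohorts <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  genes <- gene_ids(spec$n_genes)
  informative <- genes[seq_len(spec$n_informative)]
  cohorts <- vector("list", length(spec$cohort_sizes))
  latent_all <- integer(0)
  with_seed(spec$seed, {
    for (c_i in seq_along(spec$cohort_sizes)) {
      n <- spec$cohort_sizes[c_i]
      n_r <- as.integer(round(n * spec$class_balance[c_i]))
      n_r <- min(max(n_r, 1L), n - 1L)
      latent <- c(rep(0L, n - n_r), rep(1L, n_r))
      x <- matrix(stats::rnorm(spec$n_genes * n), nrow = spec$n_genes,
                  dimnames = list(genes,
                                  sprintf("C%d_S%03d", c_i, seq_len(n))))
      if (spec$n_informative > 0L && spec$effect_size > 0)
        x[informative, latent == 1L] <-
          x[informative, latent == 1L, drop = FALSE] + spec$effect_size
      x <- x * spec$cohort_scale[c_i] + spec$cohort_shift[c_i]
      if (spec$shape == "lognormal") x <- exp(x)
      labels <- latent
      if (spec$label_noise > 0) {
        flip <- stats::runif(n) < spec$label_noise
        labels[flip] <- 1L - labels[flip]
        if (length(unique(labels)) < 2L) labels <- latent  # keep both classes
      }
      cohorts[[c_i]] <- expression_cohort(x, labels, sprintf("cohort%d", c_i))
      latent_all <- c(latent_all, latent)
    }
  })
  list(cohorts = cohorts,
       ground_truth = list(informative_genes = informative,
                           latent_response = latent_all,
                           effect_size = spec$effect_size))
}

#' Simulation specification for digital-pathology marker tables
#'
#' Describes tumor/stroma protein-intensity tables for two clinical cohorts
#' (NAC: treated with neoadjuvant chemotherapy; PCT: primary chemotherapy
#' comparison cohort), with replicate tissue-microarray cores per patient and
#' survival coupled to latent response through a proportional-hazards
#' multiplier. Defaults emulate the targeted study: 55 NAC + 36 PCT patients,
#' 74 markers per compartment, three cores per patient, and response rates of
#' 21/55 (NAC) and 25/36 (PCT).
#'
#' @param n_patients length-2 integer vector, patients in the NAC and PCT
#'   cohorts.
#' @param n_markers markers per compartment.
#' @param n_predictive markers truly associated with response (planted in
#'   both compartments).
#' @param cores_per_patient replicate TMA cores per patient (>= 1); the
#'   per-patient value is the mean over cores.
#' @param effect_size standardized shift (on the per-patient mean
#'   log-intensity scale) between R and NR patients for predictive markers.
#' @param response_rate fraction of responders per cohort (length 2).
#' @param hazard_ratio hazard multiplier for latent nonresponders relative to
#'   responders (> 0).
#' @param censor_rate expected fraction of censored patients, in [0, 1).
#' @param median_os_months median overall survival of responders, months.
#' @param seed integer seed.
#' @return an object of class `pathology_sim_spec`.
#' @export
pathology_sim_spec <- function(n_patients = c(55L, 36L),
                               n_markers = 74L,
                               n_predictive = 5L,
                               cores_per_patient = 3L,
                               effect_size = 2,
                               response_rate = c(21 / 55, 25 / 36),
                               hazard_ratio = 2.5,
                               censor_rate = 0.2,
                               median_os_months = 60,
                               seed = 1L) {
  if (length(n_patients) != 2L || any(n_patients < 4L))
    stop_field("n_patients", "two cohort sizes >= 4 are required")
  if (n_predictive > n_markers)
    stop_field("n_predictive", "cannot exceed n_markers")
  if (cores_per_patient < 1L)
    stop_field("cores_per_patient", "must be >= 1")
  if (hazard_ratio <= 0) stop_field("hazard_ratio", "must be > 0")
  if (censor_rate < 0 || censor_rate >= 1)
    stop_field("censor_rate", "must lie in [0, 1)")
  structure(list(
    n_patients = as.integer(n_patients),
    n_markers = as.integer(n_markers),
    n_predictive = as.integer(n_predictive),
    cores_per_patient = as.integer(cores_per_patient),
    effect_size = effect_size,
    response_rate = rep_len(response_rate, 2L),
    hazard_ratio = hazard_ratio,
    censor_rate = censor_rate,
    median_os_months = median_os_months,
    seed = as.integer(seed)
  ), class = "pathology_sim_spec")
}

marker_ids <- function(n) sprintf("M%03d", seq_len(n))

#' Generate a synthetic digital-pathology table with survival annotations
#'
#' Marker intensities are lognormal (Gaussian on the log scale with a planted
#' response shift for predictive markers, exponentiated), measured as
#' `cores_per_patient` replicate cores whose mean is the per-patient value.
#' Overall and progression-free survival are exponential, with latent
#' nonresponders' hazard multiplied by `hazard_ratio`; censoring is
#' independent exponential calibrated to `censor_rate`.
#'
#' @param spec a [pathology_sim_spec()].
#' @return list with `table` (a `pathology_table`) and `ground_truth`
#'   (predictive markers per compartment, latent response, hazard parameters).
#' @export
generate_pathology <- function(spec) {
  stopifnot(inherits(spec, "pathology_sim_spec"))
  markers <- marker_ids(spec$n_markers)
  predictive <- markers[seq_len(spec$n_predictive)]
  n_total <- sum(spec$n_patients)
  cohort <- rep(c("NAC", "PCT"), spec$n_patients)
  pid <- sprintf("P%03d", seq_len(n_total))
  with_seed(spec$seed, {
    latent <- unlist(lapply(1:2, function(i) {
      n <- spec$n_patients[i]
      n_r <- min(max(as.integer(round(n * spec$response_rate[i])), 1L), n - 1L)
      c(rep(0L, n - n_r), rep(1L, n_r))
    }))
    make_compartment <- function() {
      cores <- array(stats::rnorm(n_total * spec$n_markers *
                                    spec$cores_per_patient, sd = 0.5),
                     dim = c(n_total, spec$n_markers, spec$cores_per_patient),
                     dimnames = list(pid, markers, NULL))
      base_level <- matrix(rep(stats::rnorm(spec$n_markers, mean = 1, sd = 0.3),
                               each = n_total),
                           nrow = n_total)
      cores <- cores + array(base_level, dim = dim(cores))
      if (spec$n_predictive > 0L && spec$effect_size > 0) {
        # core sd is 0.5 and per-patient means average the cores, so this
        # makes effect_size the standardized shift on the patient-mean scale
        shift <- spec$effect_size * 0.5 / sqrt(spec$cores_per_patient)
        idx_r <- which(latent == 1L)
        cores[idx_r, seq_len(spec$n_predictive), ] <-
          cores[idx_r, seq_len(spec$n_predictive), , drop = FALSE] + shift
      }
      exp(cores)
    }
    tumor_cores <- make_compartment()
    stroma_cores <- make_compartment()
    # exponential survival: responders at the baseline rate, nonresponders at
    # baseline * hazard_ratio; independent exponential censoring with rate
    # chosen so P(censored) ~= censor_rate for responders
    lambda0 <- log(2) / spec$median_os_months
    rate <- lambda0 * ifelse(latent == 0L, spec$hazard_ratio, 1)
    draw_endpoint <- function(mult) {
      t_event <- stats::rexp(n_total, rate * mult)
      if (spec$censor_rate > 0) {
        lam_c <- lambda0 * mult * spec$censor_rate / (1 - spec$censor_rate)
        t_cens <- stats::rexp(n_total, lam_c)
        list(time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens))
      } else list(time = t_event, event = rep(1L, n_total))
    }
    os <- draw_endpoint(1)
    pfs <- draw_endpoint(1.5)  # progression events occur earlier than death
    patients <- data.frame(
      patient_id = pid, cohort = cohort, label = latent,
      os_time = os$time, os_event = os$event,
      pfs_time = pfs$time, pfs_event = pfs$event,
      stringsAsFactors = FALSE)
  })
  tbl <- pathology_table(
    tumor = apply(tumor_cores, c(1, 2), mean),
    stroma = apply(stroma_cores, c(1, 2), mean),
    patients = patients,
    cores = list(tumor = tumor_cores, stroma = stroma_cores),
    data_type = "raw")
  list(table = tbl,
       ground_truth = list(
         predictive_markers = list(tumor = predictive, stroma = predictive),
         latent_response = latent,
         hazard_params = list(baseline = log(2) / spec$median_os_months,
                              hazard_ratio = spec$hazard_ratio)))
}

#' Digital-pathology table container
#'
#' Patients x markers intensity matrices for the tumor and stroma
#' compartments, per-patient clinical annotations (cohort, response label,
#' OS/PFS times and events) and optionally the per-core replicate values.
#'
#' @param tumor,stroma patients x markers matrices of per-patient mean
#'   intensities; shared patient and marker names.
#' @param patients data.frame with columns `patient_id`, `cohort`, `label`,
#'   `os_time`, `os_event`, `pfs_time`, `pfs_event`.
#' @param cores optional list of patients x markers x cores arrays.
#' @param data_type "raw" or "standardized".
#' @return an object of class `pathology_table`.
#' @export
pathology_table <- function(tumor, stroma, patients, cores = NULL,
                            data_type = c("raw", "standardized")) {
  data_type <- match.arg(data_type)
  tumor <- as.matrix(tumor); stroma <- as.matrix(stroma)
  if (!identical(dim(tumor), dim(stroma)) ||
      !identical(rownames(tumor), rownames(stroma)))
    stop_field("stroma", "compartments must share the patient index and markers")
  if (anyNA(tumor) || anyNA(stroma))
    stop_field("values", "marker values must be complete (impute upstream)")
  if (nrow(patients) != nrow(tumor))
    stop_field("patients", "one row per patient is required")
  structure(list(tumor = tumor, stroma = stroma, patients = patients,
                 cores = cores, data_type = data_type),
            class = "pathology_table")
}

#' @export
print.pathology_table <- function(x, ...) {
  cat(sprintf("<pathology_table (%s)> %d patients x %d markers x 2 compartments\n",
              x$data_type, nrow(x$tumor), ncol(x$tumor)))
  print(table(x$patients$cohort, x$patients$label,
              dnn = c("cohort", "label")))
  invisible(x)
}

#' Standardize a pathology table per marker
#'
#' z-scores every marker over the combined cohorts, per compartment. Core
#' replicates are dropped (ratios are only meaningful on raw intensities).
#'
#' @param table a `pathology_table` with `data_type = "raw"`.
#' @return a `pathology_table` with `data_type = "standardized"`.
#' @export
standardize_pathology <- function(table) {
  stopifnot(inherits(table, "pathology_table"))
  z <- function(m) {
    out <- apply(m, 2, function(v) {
      s <- stats::sd(v)
      if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
    })
    dimnames(out) <- dimnames(m)
    out
  }
  pathology_table(z(table$tumor), z(table$stroma), table$patients,
                  cores = NULL, data_type = "standardized")
}
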