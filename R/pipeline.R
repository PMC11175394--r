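#' Run the full linkage stage
#'
#' Standardizes both record sets, blocks and compares candidate pairs,
#' trains the match classifier on truth-labelled pairs, deduplicates the
#' HIV records and links cancer records to the resulting clusters. The
#' training sample mixes within-HIV pairs with cancer-HIV pairs (the two
#' comparison spaces the model must score: cross-set pairs systematically
#' lack the shared facility identifiers that duplicate HIV records carry).
#' Uses the current RNG stream (training-pair sampling) so a pipeline run
#' is reproducible end-to-end under one seed.
#'
#' @param hiv,cancer Record tibbles (as from [simulate_records()]).
#' @param truth Truth table `record_id`, `entity_id` used to label
#'   training pairs (generator truth or clerical labels).
#' @param n_train Number of labelled pairs used for training.
#' @return A list: `hiv_std`, `cancer_std`, `model`, `decisions`,
#'   `clusters`, `links`, `pair_labels` and `train_idx` (truth labels of
#'   all candidate pairs and the training rows, for held-out evaluation
#'   via [holdout_pair_metrics()]).
#' @export
run_linkage <- function(hiv, cancer, truth, n_train = 5000) {
  hiv_std <- standardize_records(hiv)
  cancer_std <- standardize_records(cancer)
  pairs <- candidate_pairs(hiv_std)
  feats <- compare_pairs(pairs, hiv_std)
  rm(pairs)
  split <- make_training_pairs(feats, truth, n_train = n_train)
  cross_pairs <- candidate_pairs(cancer_std, hiv_std)
  cross_feats <- if (nrow(cross_pairs) > 0) {
    compare_pairs(cross_pairs, cancer_std, hiv_std)
  } else {
    NULL
  }
  train <- split$train
  if (!is.null(cross_feats)) {
    cross_split <- tryCatch(
      make_training_pairs(cross_feats, truth, n_train = n_train %/% 2),
      error = function(e) NULL  # e.g. no true cross matches in tiny runs
    )
    if (!is.null(cross_split)) {
      train <- dplyr::bind_rows(train, cross_split$train)
    }
  }
  model <- fit_match_classifier(train)
  decisions <- predict(model, feats)
  rm(feats)
  gc(verbose = FALSE)
  clusters <- deduplicate(decisions, hiv_std$record_id)
  links <- link_cancer(cancer_std, hiv_std, clusters, model,
                       features = cross_feats)
  list(hiv_std = hiv_std, cancer_std = cancer_std, model = model,
       decisions = decisions, clusters = clusters, links = links,
       pair_labels = split$labels, train_idx = split$train_idx)
}

#' Run the end-to-end pipeline
#'
#' simulate -> standardize -> link -> cohort -> tables, under a single
#' seed. When `out_dir` is given, every stage output is written
#' (`hiv_records.csv`, `cancer_records.csv`, `truth.csv`, `clusters.csv`,
#' `links.csv`, `model.json`, `cases.csv`, `attrition.json`, `table1.csv`,
#' `table2.csv`, `table3.csv`, `flows.geojson`, `manifest.json`). Identical
#' configuration and seed produce byte-identical CSV outputs.
#'
#' @param config An [sim_config()] (or a path to a YAML configuration).
#' @param out_dir Optional output directory.
#' @param n_train Labelled pairs for classifier training.
#' @return A list of class `hcm_run`: the simulation, linkage stage,
#'   cohort, tables (`od`, `demographics`, `logistic`, `flows`), linkage
#'   `evaluation`, and the run `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, n_train = 5000) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  sim <- simulate_records(config)
  linked <- run_linkage(sim$hiv, sim$cancer, sim$truth, n_train = n_train)
  cohort <- build_cases(linked$hiv_std, linked$clusters, linked$links,
                        linked$cancer_std)
  od <- od_matrix(cohort$cases)
  demographics <- demographics_table(cohort$cases)
  logistic <- tryCatch(logistic_fit(cohort$cases),
                       error = function(e) {
                         message("logistic stage skipped: ", conditionMessage(e))
                         NULL
                       })
  flows <- export_flows(od)
  evaluation <- evaluate_linkage(linked$clusters, sim$truth, linked$links,
                                 cancer_ids = sim$cancer$record_id)
  manifest <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    counts = list(
      entities = nrow(sim$entities),
      hiv_records = nrow(sim$hiv),
      cancer_records = nrow(sim$cancer),
      candidate_pairs = nrow(linked$decisions),
      clusters = dplyr::n_distinct(linked$clusters$cluster_id),
      links = nrow(linked$links),
      cases = nrow(cohort$cases)
    ),
    attrition = as.list(cohort$attrition),
    linkage_quality = as.list(evaluation),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  run <- structure(
    list(sim = sim, linkage = linked, cohort = cohort,
         tables = list(od = od, demographics = demographics,
                       logistic = logistic, flows = flows),
         evaluation = evaluation, manifest = manifest, config = config),
    class = "hcm_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.hcm_run <- function(x, ...) {
  cat("<hcm_run> seed", x$config$seed, "\n")
  cat("  counts:", paste(names(x$manifest$counts), unlist(x$manifest$counts),
                         sep = "=", collapse = ", "), "\n")
  cat(sprintf("  dedup precision/recall: %.4f / %.4f\n",
              x$evaluation$pairwise_precision, x$evaluation$pairwise_recall))
  invisible(x)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_simulation(run$sim, out_dir)
  readr::write_csv(run$linkage$clusters, file.path(out_dir, "clusters.csv"))
  readr::write_csv(run$linkage$links, file.path(out_dir, "links.csv"))
  write_match_model(run$linkage$model, file.path(out_dir, "model.json"))
  readr::write_csv(run$cohort$cases, file.path(out_dir, "cases.csv"))
  jsonlite::write_json(as.list(run$cohort$attrition),
                       file.path(out_dir, "attrition.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  readr::write_csv(run$tables$demographics$table, file.path(out_dir, "table1.csv"))
  readr::write_csv(od_format(run$tables$od), file.path(out_dir, "table2.csv"))
  if (!is.null(run$tables$logistic)) {
    readr::write_csv(tidy(run$tables$logistic), file.path(out_dir, "table3.csv"))
  }
  write_flows_geojson(run$tables$flows, file.path(out_dir, "flows.geojson"))
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

schema_defs <- function() {
  list(
    hiv = list(
      required = c("record_id", "first_name", "surname", "dob", "age",
                   "episode_number", "folder_number", "test_type",
                   "result_label", "facility_id", "province", "test_date"),
      province_cols = "province", date_cols = c("dob", "test_date"),
      label_cols = list(result_label = hiv_result_labels())
    ),
    cancer = list(
      required = c("record_id", "first_name", "surname", "dob", "age",
                   "episode_number", "folder_number", "cancer_type", "basis",
                   "facility_id", "diagnosis_province", "diagnosis_date"),
      province_cols = "diagnosis_province",
      date_cols = c("dob", "diagnosis_date"),
      label_cols = list(basis = c("histology", "cytology", "bone-marrow"))
    ),
    truth = list(required = c("record_id", "entity_id"),
                 province_cols = character(), date_cols = character(),
                 label_cols = list()),
    cases = list(
      required = c("cluster_id", "sex", "race", "age_at_diagnosis",
                   "home_province", "diagnosis_province", "cancer_type",
                   "hiv_first_date", "cancer_diagnosis_date", "out_of_province"),
      province_cols = c("home_province", "diagnosis_province"),
      date_cols = c("hiv_first_date", "cancer_diagnosis_date"),
      label_cols = list(sex = c("F", "M"))
    )
  )
}

#' Validate a file or table against a pipeline schema
#'
#' Checks column presence, date parseability, province-code vocabulary and
#' categorical labels for the `hiv`, `cancer`, `truth` or `cases` schema.
#' Violations are returned, not raised.
#'
#' @param x A data frame, or path to a CSV file.
#' @param schema One of `"hiv"`, `"cancer"`, `"truth"`, `"cases"`.
#' @return A tibble of violations (`row`, `column`, `problem`); zero rows
#'   means the input conforms.
#' @export
validate_schema <- function(x, schema = c("hiv", "cancer", "truth", "cases")) {
  schema <- match.arg(schema)
  def <- schema_defs()[[schema]]
  if (is.character(x)) {
    if (!file.exists(x)) stop("file not found: ", x, call. = FALSE)
    x <- readr::read_csv(x, col_types = readr::cols(.default = readr::col_character()))
  }
  violations <- list()
  add <- function(row, column, problem) {
    violations[[length(violations) + 1]] <<-
      tibble::tibble(row = row, column = column, problem = problem)
  }
  missing_cols <- setdiff(def$required, names(x))
  for (col in missing_cols) add(NA_integer_, col, "missing column")
  for (col in setdiff(def$province_cols, missing_cols)) {
    v <- as.character(x[[col]])
    bad <- which(!is.na(v) & v != "" & !(v %in% province_codes()))
    for (i in bad) add(i, col, paste0("invalid province code: ", v[i]))
  }
  for (col in setdiff(def$date_cols, missing_cols)) {
    v <- as.character(x[[col]])
    parsed <- as.Date(v, format = "%Y-%m-%d", optional = TRUE)
    bad <- which(!is.na(v) & v != "" & is.na(parsed))
    for (i in bad) add(i, col, paste0("unparseable date: ", v[i]))
  }
  for (col in setdiff(names(def$label_cols), missing_cols)) {
    allowed <- def$label_cols[[col]]
    v <- as.character(x[[col]])
    bad <- which(!is.na(v) & v != "" & !(v %in% allowed))
    for (i in bad) add(i, col, paste0("invalid label: ", v[i]))
  }
  if (length(violations) == 0) {
    tibble::tibble(row = integer(), column = character(), problem = character())
  } else {
    dplyr::bind_rows(violations)
  }
}
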