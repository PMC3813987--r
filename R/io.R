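# Configuration files (YAML), tabular outcomes (CSV), and the command-line
# entry points built on them. The YAML schemas are deliberately small and
# validated with actionable messages.

#' Read and write weight-matrix configuration files
#'
#' The YAML schema has a \code{toxicities} list (each entry: \code{name},
#' five \code{weights}, five \code{dlt} flags), the normalization constant
#' \code{nu}, and the normalized target \code{theta_star}.
#'
#' @param path file path.
#' @return \code{read_weight_config}: a list with \code{weights} (an
#'   [weight_matrix()]), \code{nu}, \code{theta_star}.
#' @export
read_weight_config <- function(path) {
  cfg <- read_yaml_file(path)
  need <- c("toxicities", "nu", "theta_star")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("weight config ", path, " is missing field(s): ",
         paste(miss, collapse = ", "))
  tox <- cfg$toxicities
  if (!is.list(tox) || !length(tox))
    stop("'toxicities' must be a nonempty list")
  wm <- t(vapply(tox, function(t) as.numeric(unlist(t$weights)), numeric(5)))
  dm <- t(vapply(tox, function(t) as.logical(unlist(t$dlt)), logical(5)))
  nms <- vapply(tox, function(t) as.character(t$name), "")
  w <- weight_matrix(wm, dm, toxicities = nms)
  nu <- as.numeric(cfg$nu)
  theta_star <- as.numeric(cfg$theta_star)
  if (theta_star <= 0 || theta_star >= 1)
    stop("'theta_star' must lie in (0, 1)")
  if (nu <= ttp_max(w))
    stop("'nu' must exceed the maximal TTP of the weight matrix (",
         format(ttp_max(w), digits = 6), ")")
  list(weights = w, nu = nu, theta_star = theta_star)
}

#' @rdname read_weight_config
#' @param w an [weight_matrix()].
#' @param nu,theta_star normalization constant and normalized target.
#' @export
write_weight_config <- function(w, nu, theta_star, path) {
  stopifnot(inherits(w, "nttp_weights"))
  tox <- lapply(seq_along(w$toxicities), function(l)
    list(name = w$toxicities[l], weights = as.numeric(w$w[l, ]),
         dlt = as.logical(w$dlt[l, ])))
  yaml::write_yaml(list(toxicities = tox, nu = nu, theta_star = theta_star),
                   path)
  invisible(path)
}

#' Read and write scenario configuration files
#'
#' The YAML schema has a \code{toxicities} list (each entry: \code{name}
#' and \code{probs}, a list of K rows of 5 grade probabilities) and an
#' optional \code{true_rd}.
#'
#' @param path file path.
#' @return \code{read_scenario_config}: an [scenario()].
#' @export
read_scenario_config <- function(path) {
  cfg <- read_yaml_file(path)
  if (is.null(cfg$toxicities))
    stop("scenario config ", path, " is missing the 'toxicities' list")
  P <- lapply(cfg$toxicities, function(t) {
    m <- do.call(rbind, lapply(t$probs, as.numeric))
    rs <- rowSums(m)
    if (any(abs(rs - 1) > 1e-6))
      stop("scenario rows must sum to 1; worst deviation ",
           format(max(abs(rs - 1)), digits = 3))
    m / rs      # absorb serialization round-off
  })
  names(P) <- vapply(cfg$toxicities, function(t) as.character(t$name), "")
  scenario(P, true_rd = cfg$true_rd)
}

#' @rdname read_scenario_config
#' @param sc an [scenario()].
#' @export
write_scenario_config <- function(sc, path) {
  stopifnot(inherits(sc, "nttp_scenario"))
  tox <- lapply(seq_len(sc$L), function(l)
    list(name = names(sc$P)[l],
         probs = lapply(seq_len(sc$K), function(k) as.numeric(sc$P[[l]][k, ]))))
  out <- list(toxicities = tox)
  if (!is.null(sc$true_rd)) out$true_rd <- sc$true_rd
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

read_yaml_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  yaml::read_yaml(path)
}

#' Score a table of patient toxicity grades
#'
#' Reads a CSV of per-patient grades (one column per toxicity type, in the
#' weight-config order, plus any identifier columns), appends \code{ttp},
#' \code{nttp}, and \code{dlt} columns, and optionally writes the result.
#'
#' @param grades_file CSV of grades; toxicity columns are matched by the
#'   weight config's toxicity names when present, otherwise the last L
#'   numeric columns are used.
#' @param weights_file weight-matrix YAML (see [read_weight_config()]).
#' @param out optional output CSV path.
#' @return The scored data frame, invisibly when \code{out} is given.
#' @export
cli_score <- function(grades_file, weights_file, out = NULL) {
  wc <- read_weight_config(weights_file)
  if (!file.exists(grades_file)) stop("file not found: ", grades_file)
  df <- utils::read.csv(grades_file)
  if (nrow(df) == 0L) stop("grades file ", grades_file, " has no rows")
  nms <- wc$weights$toxicities
  if (all(nms %in% names(df))) {
    g <- as.matrix(df[, nms, drop = FALSE])
  } else {
    num <- names(df)[vapply(df, is.numeric, TRUE)]
    if (length(num) < length(nms))
      stop("grades file must contain a grade column per toxicity type (",
           paste(nms, collapse = ", "), ")")
    g <- as.matrix(df[, utils::tail(num, length(nms)), drop = FALSE])
  }
  df$ttp <- ttp(g, wc$weights)
  df$nttp <- nttp(g, wc$weights, wc$nu)
  df$dlt <- is_dlt(g, wc$weights)
  if (!is.null(out)) {
    utils::write.csv(df, out, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Exact scenario moments as a table
#'
#' Computes the per-dose mean nTTP and DLT probability of a scenario file
#' by full profile enumeration and optionally writes them as CSV.
#'
#' @param scenario_file scenario YAML (see [read_scenario_config()]).
#' @inheritParams cli_score
#' @return The moments data frame (\code{dose}, \code{mean_nttp},
#'   \code{p_dlt}), invisibly when \code{out} is given.
#' @export
cli_moments <- function(scenario_file, weights_file, out = NULL) {
  wc <- read_weight_config(weights_file)
  sc <- read_scenario_config(scenario_file)
  mom <- scenario_moments(sc, wc$weights, wc$nu)
  if (!is.null(out)) {
    utils::write.csv(mom, out, row.names = FALSE)
    return(invisible(mom))
  }
  mom
}

design_from_list <- function(d, theta_star) {
  args <- d[intersect(names(d),
                      setdiff(names(formals(design_config)), "theta_star"))]
  args$theta_star <- theta_star
  do.call(design_config, args)
}

# Tiny FNV-1a hash of a string, for manifest provenance stamps.
fnv1a <- function(txt) {
  h <- 2166136261
  for (b in as.integer(charToRaw(txt))) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Run a simulation study from a run-configuration file
#'
#' The run config YAML names the weight and scenario files and holds the
#' design block(s), seed, and replicate count:
#' \preformatted{
#' weights: weights.yaml
#' scenario: scenario.yaml
#' seed: 1
#' n_reps: 1000
#' design:
#'   method: qlcrm     # or a list of methods, or "all"
#'   n_total: 36
#' }
#' Writes one summary CSV per method, a per-trial CSV (recommended dose and
#' DLT count for every replicate), and a JSON manifest recording the seed,
#' package version, and the full configuration with its hash -- enough to
#' reproduce the run bit for bit.
#'
#' @param config_file run-configuration YAML path.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the list of \code{"nttp_sim"} summaries by method.
#' @export
cli_simulate <- function(config_file, out_dir) {
  cfg <- read_yaml_file(config_file)
  for (f in c("weights", "scenario", "design"))
    if (is.null(cfg[[f]])) stop("run config is missing the '", f, "' field")
  base <- dirname(normalizePath(config_file))
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  wc <- read_weight_config(resolve(cfg$weights))
  sc <- read_scenario_config(resolve(cfg$scenario))
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  n_reps <- if (is.null(cfg$n_reps)) 1000L else as.integer(cfg$n_reps)
  d <- cfg$design
  methods <- d$method
  if (is.null(methods)) methods <- "qlcrm"
  if (identical(methods, "all")) methods <- c("qlcrm", "qcrm", "eid", "ua")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sims <- list()
  for (m in methods) {
    d$method <- m
    des <- design_from_list(d, wc$theta_star)
    sm <- simulate_design(sc, des, wc$weights, wc$nu,
                          n_reps = n_reps, seed = seed)
    sims[[m]] <- sm
    utils::write.csv(summarize_tables(list(sm)),
                     file.path(out_dir, paste0("summary_", m, ".csv")),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(trial = seq_len(n_reps), recommended = sm$recommended,
                 n_dlt = sm$dlt_counts),
      file.path(out_dir, paste0("trials_", m, ".csv")), row.names = FALSE)
  }
  cfg_txt <- paste(readLines(config_file, warn = FALSE), collapse = "\n")
  manifest <- list(seed = seed, n_reps = n_reps, methods = methods,
                   package_version = as.character(utils::packageVersion("nttp")),
                   config_hash = fnv1a(cfg_txt), config = cfg)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(sims)
}

#' Run and report a single simulated trial from config files
#'
#' @inheritParams cli_simulate
#' @param weights_file,scenario_file configuration files.
#' @param method design method.
#' @param seed integer seed.
#' @param n_total,cohort_size accrual structure.
#' @param out optional CSV path for the per-patient trial record.
#' @return The \code{"nttp_trial"} record, invisibly when \code{out} is
#'   given.
#' @export
cli_trial <- function(scenario_file, weights_file, method = "qlcrm",
                      seed = 1L, n_total = 36L, cohort_size = 3L,
                      out = NULL) {
  wc <- read_weight_config(weights_file)
  sc <- read_scenario_config(scenario_file)
  des <- design_config(method, theta_star = wc$theta_star, K = sc$K,
                       n_total = n_total, cohort_size = cohort_size)
  tr <- run_trial(sc, des, wc$weights, wc$nu, seed = seed)
  if (!is.null(out)) {
    utils::write.csv(as.data.frame(tr), out, row.names = FALSE)
    return(invisible(tr))
  }
  tr
}
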