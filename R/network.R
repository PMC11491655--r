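#' Build the simulated one-subject-per-client network
#'
#' Every subject becomes one client holding exactly their two eye-level
#' records. Record integrity (one L and one R per subject, shared
#' age/center/group) is enforced; violations raise an error naming the
#' subject. The resulting network is invariant to the row order of the
#' input cohort (clients are sorted by subject id).
#'
#' @param cohort a `fedgap_cohort`.
#' @return object of class `fedgap_network`: list with `cohort`, `subjects`
#'   (one row per client: `subject_id`, `age`, `center_id`, `group`) and
#'   `rows` (integer matrix, one row per client giving the indices of its
#'   two records in `cohort$features`).
#' @export
build_network <- function(cohort) {
  stopifnot(inherits(cohort, "fedgap_cohort"))
  meta <- cohort$meta
  validate_record_pairs(meta)
  ord <- order(meta$subject_id, meta$eye)
  idx <- matrix(ord, ncol = 2L, byrow = TRUE) # col 1 = L, col 2 = R
  first <- idx[, 1L]
  subjects <- data.frame(subject_id = meta$subject_id[first],
                         age = meta$age[first],
                         center_id = meta$center_id[first],
                         group = meta$group[first],
                         stringsAsFactors = FALSE)
  structure(list(cohort = cohort, subjects = subjects, rows = idx),
            class = "fedgap_network")
}

#' @export
print.fedgap_network <- function(x, ...) {
  cat(sprintf("Simulated client network: %d clients (2 records each)\n",
              nrow(x$subjects)))
  tab <- table(x$subjects$center_id)
  cat("  centers:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Monte-Carlo split plan
#'
#' Describes repeated random train/validation splits: `n_val` healthy
#' subjects are drawn without replacement from the training centers, then
#' `n_train` from the remainder; every subject from a test center is an
#' external-test client. Images of one subject never straddle roles.
#'
#' @param n_train number of training clients; the shipped experiments use
#'   150, 300, 600, 1200 or 2400.
#' @param n_val number of internal-validation clients (default 1200).
#' @param train_centers,test_centers character vectors of center ids; the
#'   defaults split 8 centers 5/3.
#' @param mc_iterations number of Monte-Carlo iterations (default 10).
#' @param seed integer seed; together with the iteration index it fully
#'   determines the assignment.
#' @return an object of class `split_plan`.
#' @export
split_plan <- function(n_train, n_val = 1200,
                       train_centers = sprintf("C%d", 1:5),
                       test_centers = sprintf("C%d", 6:8),
                       mc_iterations = 10, seed = 1) {
  check_scalar(n_train, "n_train", min = 1, integer = TRUE)
  check_scalar(n_val, "n_val", min = 1, integer = TRUE)
  check_scalar(mc_iterations, "mc_iterations", min = 1, integer = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  if (length(intersect(train_centers, test_centers)) > 0) {
    stop_param("train_centers and test_centers overlap: %s",
               paste(intersect(train_centers, test_centers), collapse = ","))
  }
  structure(list(n_train = as.integer(n_train), n_val = as.integer(n_val),
                 train_centers = train_centers, test_centers = test_centers,
                 mc_iterations = as.integer(mc_iterations),
                 seed = as.integer(seed)),
            class = "split_plan")
}

#' One Monte-Carlo role assignment
#'
#' Deterministic under `(plan$seed, iteration)`. Only healthy clients from
#' the training centers are eligible for train/validation roles;
#' validation clients are drawn first, then training clients from the
#' remainder. All clients from the test centers (healthy and disease) are
#' assigned the external-test role; disease clients from training centers
#' are left unassigned, mirroring a network in which only healthy subjects
#' participate in training.
#'
#' @param network a [build_network()] result.
#' @param plan a [split_plan()].
#' @param iteration Monte-Carlo iteration index in `1..mc_iterations`.
#' @return list with `iteration` and character vectors `train`, `val`,
#'   `external` of subject ids.
#' @export
monte_carlo_split <- function(network, plan, iteration) {
  stopifnot(inherits(network, "fedgap_network"), inherits(plan, "split_plan"))
  check_scalar(iteration, "iteration", min = 1, max = plan$mc_iterations,
               integer = TRUE)
  subj <- network$subjects
  eligible <- subj$subject_id[subj$group == "healthy" &
                                subj$center_id %in% plan$train_centers]
  need <- plan$n_train + plan$n_val
  if (need > length(eligible)) {
    stop_param(paste0("n_train + n_val = %d exceeds the %d healthy clients",
                      " in the training centers"),
               need, length(eligible))
  }
  external <- subj$subject_id[subj$center_id %in% plan$test_centers]
  with_seed(derive_seed(plan$seed, paste0("split/", iteration)), {
    val <- sample(eligible, plan$n_val)
    train <- sample(setdiff(eligible, val), plan$n_train)
    list(iteration = as.integer(iteration),
         train = train, val = val, external = external)
  })
}

#' Write / read a split manifest as JSON
#'
#' @param split a [monte_carlo_split()] result.
#' @param path JSON path.
#' @return `write_split()` returns `path` invisibly; `read_split()` the
#'   split list.
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(split, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  s$iteration <- as.integer(s$iteration)
  s
}

# internal: pooled record matrices for a set of subject ids
pool_records <- function(network, ids) {
  keep <- match(ids, network$subjects$subject_id)
  if (anyNA(keep)) {
    stop_param("unknown subject id: %s", ids[which(is.na(keep))[1]])
  }
  rows <- as.integer(t(network$rows[keep, , drop = FALSE]))
  list(X = network$cohort$features[rows, , drop = FALSE],
       y = network$cohort$meta$age[rows])
}
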