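# Independent oracles used across tests. These deliberately avoid the
# package's own computational paths: brute-force search, direct enumeration
# and derivative-free optimisation only.

# brute-force nearest-TRUE-cell distance (cell-centre metric)
brute_force_distance <- function(mask) {
  v <- mask$values
  true_idx <- which(v, arr.ind = TRUE)
  out <- matrix(Inf, nrow(v), ncol(v))
  if (nrow(true_idx) == 0) {
    return(out)
  }
  for (i in seq_len(nrow(v))) {
    for (j in seq_len(ncol(v))) {
      out[i, j] <- sqrt(min((i - true_idx[, 1])^2 + (j - true_idx[, 2])^2))
    }
  }
  out * mask$cellsize
}

# enumerated conditional log-likelihood (plain loops, no shared code)
enum_clogit_negll <- function(beta, data, covariates) {
  total <- 0
  for (sid in unique(data$stratum_id)) {
    rows <- data[data$stratum_id == sid, , drop = FALSE]
    eta <- as.matrix(rows[, covariates, drop = FALSE]) %*% beta
    total <- total + (log(sum(exp(eta))) - eta[rows$case == 1])
  }
  as.numeric(total)
}

# derivative-free maximiser of the enumerated likelihood
oracle_clogit <- function(data, covariates) {
  opt <- stats::optim(
    par = rep(0, length(covariates)),
    fn = enum_clogit_negll, data = data, covariates = covariates,
    method = "Nelder-Mead",
    control = list(maxit = 50000, reltol = 1e-14)
  )
  # polish with a second restart so the simplex reaches 1e-6 accuracy
  opt <- stats::optim(
    par = opt$par,
    fn = enum_clogit_negll, data = data, covariates = covariates,
    method = "Nelder-Mead",
    control = list(maxit = 50000, reltol = 1e-15)
  )
  stats::setNames(opt$par, covariates)
}

# matched strata generated directly from the choice model: K + 1 candidate
# covariate rows per stratum, the "used" one drawn by softmax(beta . x)
make_choice_strata <- function(n_strata, k, beta, n_animals = 5, seed = 1) {
  set.seed(seed)
  p <- length(beta)
  covs <- paste0("x", seq_len(p))
  rows <- vector("list", n_strata)
  for (s in seq_len(n_strata)) {
    X <- matrix(rnorm((k + 1) * p), k + 1, p)
    eta <- drop(X %*% beta)
    pick <- sample.int(k + 1, 1, prob = exp(eta - max(eta)))
    case <- integer(k + 1)
    case[pick] <- 1L
    df <- tibble::as_tibble(as.data.frame(X))
    names(df) <- covs
    df$stratum_id <- s
    df$case <- case
    df$animal_id <- ((s - 1) %% n_animals) + 1
    rows[[s]] <- df
  }
  list(data = dplyr::bind_rows(rows), covariates = covs)
}

# tiny scenario/world reused by extraction tests
tiny_world <- function(seed = 2, rows = 40, cols = 40, cell = 200, ...) {
  sc <- migration_scenario(
    seed = seed, grid_size = c(rows, cols), cell_size = cell, ...
  )
  dem <- make_landscape(sc)
  fields <- make_dynamic_fields(sc, dem)
  list(
    scenario = sc, dem = dem, fields = fields,
    world = prepare_sim_world(sc, dem, fields)
  )
}

# phenology parameter rasters from a scenario's generating truth
truth_pheno_rasters <- function(tw) {
  tr <- tw$fields$truth
  g <- function(m) {
    out <- tw$dem
    out$values <- if (is.matrix(m)) m else matrix(m, nrow(tw$dem$values), ncol(tw$dem$values))
    out
  }
  list(
    greenup_doy = g(tr$xmidS_ndvi),
    scalS = g(tr$scalS_ndvi),
    xmidA_ndvi = g(tr$xmidA_ndvi),
    scalA = g(tr$scalA_ndvi),
    lo = g(tr$ndvi_lo),
    hi = g(tr$ndvi_hi),
    snowmelt_doy = g(snowday_to_doy(tr$xmidA_fsc))
  )
}
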