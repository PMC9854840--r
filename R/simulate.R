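# Synthetic-data generator: breeding designs and landmark phenotypes with
# known covariance components, for end-to-end verification by parameter
# recovery.

#' Symmetric template of the 40-landmark viper head scheme
#'
#' A synthetic, exactly bilaterally symmetric dorsal head configuration
#' laid out to resemble a viperid head in dorsal view (snout up, midline
#' on the y axis), centred and scaled to unit centroid size. It is a
#' stand-in constructed for simulation; it is not digitized from any
#' specimen.
#'
#' @return A 40 x 2 coordinate matrix matching [viper_head_scheme()].
#' @export
viper_head_template <- function() {
  X <- matrix(NA_real_, 40L, 2L)
  right <- rbind(
    c(2L,  0.12, 0.95), c(4L,  0.20, 0.82), c(6L,  0.26, 0.66),
    c(8L,  0.30, 0.52), c(10L, 0.36, 0.18), c(12L, 0.30, 0.10),
    c(14L, 0.22, 0.12), c(16L, 0.48, -0.35),
    c(18L, 0.345, 0.42), c(20L, 0.37, 0.30),
    c(22L, 0.40, 0.05), c(24L, 0.43, -0.08), c(26L, 0.455, -0.18),
    c(28L, 0.475, -0.27),
    c(30L, 0.10, 0.45), c(32L, 0.11, 0.15),
    c(36L, 0.12, 0.02), c(38L, 0.14, -0.30))
  X[right[, 1L], ] <- right[, 2:3]
  X[right[, 1L] + 1L, ] <- cbind(-right[, 2L], right[, 3L])
  X[1L, ] <- c(0, 1.00)
  X[34L, ] <- c(0, 0.10)
  X[35L, ] <- c(0, 0.05)
  X[40L, ] <- c(0, -0.42)
  X <- sweep(X, 2L, colMeans(X))
  X[abs(X) < 1e-15] <- 0
  unname(X / sqrt(sum(X^2)))
}

# Orthonormal basis (2k x (2p + m - 2)) of the symmetric shape tangent
# space at a symmetric template: symmetric coordinate perturbations with
# y-translation and the scale (template) direction projected out.
symmetric_basis_ <- function(template, scheme) {
  k <- nrow(template)
  modes <- list()
  for (r in seq_len(nrow(scheme$pairs))) {
    l <- scheme$pairs[r, 1L]; rr <- scheme$pairs[r, 2L]
    mx <- numeric(2L * k); mx[l] <- 1; mx[rr] <- -1       # mirrored x shift
    my <- numeric(2L * k); my[k + l] <- 1; my[k + rr] <- 1 # shared y shift
    modes <- c(modes, list(mx, my))
  }
  for (md in scheme$midline) {
    my <- numeric(2L * k); my[k + md] <- 1
    modes <- c(modes, list(my))
  }
  M <- do.call(cbind, modes)
  # remove y-translation and uniform scaling at the template
  ty <- c(rep(0, k), rep(1, k)); ty <- ty / sqrt(sum(ty^2))
  sc <- flatten_(template); sc <- sc / sqrt(sum(sc^2))
  M <- M - ty %*% crossprod(ty, M) - sc %*% crossprod(sc, M)
  sv <- svd(M)
  keep <- sv$d > 1e-8 * sv$d[1L]
  sv$u[, keep, drop = FALSE]
}

#' Simulate a cross-classified breeding pedigree
#'
#' Families are distinct (dam, sire) pairs; dams and sires may be reused
#' across families (the study design this emulates crossed 8 dams and
#' 6 sires into 12 families), and every dam and sire appears in at least
#' one family. Offspring sex is drawn at random; dams are female and sires
#' male.
#'
#' @param n_dams,n_sires Numbers of founder dams and sires.
#' @param n_families Number of distinct dam x sire pairs; must be at least
#'   `max(n_dams, n_sires)` and at most `n_dams * n_sires`.
#' @param offspring_per_family Integer vector of length `n_families`.
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return A [pedigree()] with `sex` and `family` columns.
#' @export
simulate_pedigree <- function(n_dams, n_sires, n_families,
                              offspring_per_family, seed = 1L) {
  if (n_families > n_dams * n_sires)
    stop(sprintf("%d distinct pairs requested but only %d dam x sire pairs exist",
                 n_families, n_dams * n_sires), call. = FALSE)
  if (n_families < max(n_dams, n_sires))
    stop("need at least max(n_dams, n_sires) families so every parent is used",
         call. = FALSE)
  if (length(offspring_per_family) != n_families ||
      any(offspring_per_family < 1L))
    stop("offspring_per_family must have one entry >= 1 per family",
         call. = FALSE)
  dams <- sprintf("D%02d", seq_len(n_dams))
  sires <- sprintf("S%02d", seq_len(n_sires))
  pairs <- with_seed_(seed, {
    for (attempt in seq_len(1000L)) {
      fd <- c(sample(dams), sample(dams, n_families - n_dams, replace = TRUE))
      slots <- sample.int(n_families, n_sires)
      fs <- sample(sires, n_families, replace = TRUE)
      fs[slots] <- sample(sires)
      if (!anyDuplicated(paste(fd, fs))) break
    }
    if (anyDuplicated(paste(fd, fs)))
      stop("could not sample distinct dam x sire pairs", call. = FALSE)
    list(dam = fd, sire = fs,
         sex = sample(c("F", "M"), sum(offspring_per_family),
                      replace = TRUE))
  })
  off_ids <- sprintf("O%03d", seq_len(sum(offspring_per_family)))
  fam <- rep(sprintf("F%02d", seq_len(n_families)), offspring_per_family)
  pedigree(
    id = c(dams, sires, off_ids),
    dam = c(rep(NA, n_dams + n_sires), rep(pairs$dam, offspring_per_family)),
    sire = c(rep(NA, n_dams + n_sires), rep(pairs$sire, offspring_per_family)),
    sex = c(rep("F", n_dams), rep("M", n_sires), pairs$sex),
    family = c(rep(NA, n_dams + n_sires), fam))
}

#' Simulate additive-genetic (breeding) values down a pedigree
#'
#' Founders are drawn from N(0, G); each non-founder is the parent average
#' plus a Mendelian-sampling deviation with covariance
#' `(1/2 - (F_dam + F_sire)/4) G` (inbreeding coefficients from the
#' relationship-matrix diagonal; an unknown parent contributes zero and
#' widens the sampling variance accordingly).
#'
#' @param ped A [pedigree()].
#' @param G t x t positive-semidefinite genetic covariance matrix.
#' @param seed Integer seed.
#' @return n x t matrix of breeding values, rows in pedigree order with
#'   ids as rownames.
#' @export
simulate_breeding_values <- function(ped, G, seed = 1L) {
  G <- check_psd_(as.matrix(G), label = "G")
  t <- nrow(G)
  n <- nrow(ped)
  Fcoef <- diag(relationship_matrix(ped)) - 1
  idx <- seq_len(n)
  names(idx) <- ped$id
  a <- matrix(0, n, t, dimnames = list(ped$id, NULL))
  with_seed_(seed, {
    for (i in idx) {
      d <- ped$dam[i]; s <- ped$sire[i]
      if (is.na(d) && is.na(s)) {
        a[i, ] <- rmvn_(1L, G)
      } else {
        mu <- numeric(t); w <- 1
        if (!is.na(d)) { mu <- mu + a[idx[d], ] / 2
                         w <- w - 0.25 * (1 + Fcoef[idx[d]]) }
        if (!is.na(s)) { mu <- mu + a[idx[s], ] / 2
                         w <- w - 0.25 * (1 + Fcoef[idx[s]]) }
        a[i, ] <- mu + rmvn_(1L, w * G)
      }
    }
  })
  a
}

#' Define the true generative model for a simulation
#'
#' Holds everything the generator needs: the symmetric landmark template
#' and scheme, the true covariance components (in the symmetric-basis
#' trait space), the allometric slope on log centroid size, the log
#' centroid-size distribution, the asymmetric digitization noise level,
#' and the seed.
#'
#' @param G,Mat,Pat,R t x t symmetric PSD matrices (t at most the
#'   symmetric-space dimension, 38 for the built-in scheme).
#' @param beta Length-t allometric slope per unit log centroid size.
#' @param cs_mean,cs_sd Mean and SD of log centroid size (log image units).
#' @param asym_noise_sd SD of i.i.d. digitization noise added to each
#'   landmark coordinate (shape units, i.e., relative to unit centroid
#'   size) before the similarity transform; this noise is asymmetric and
#'   is what the symmetric component removes.
#' @param seed Integer seed.
#' @param template Symmetric k x 2 template (default
#'   [viper_head_template()]).
#' @param scheme Matching [landmark_scheme()].
#' @return Object of class `simulation_truth`.
#' @export
simulation_truth <- function(G, Mat, Pat, R, beta = NULL,
                             cs_mean = log(25), cs_sd = 0.15,
                             asym_noise_sd = 0.002, seed = 1L,
                             template = viper_head_template(),
                             scheme = viper_head_scheme()) {
  G <- check_psd_(as.matrix(G), label = "G")
  Mat <- check_psd_(as.matrix(Mat), label = "Mat")
  Pat <- check_psd_(as.matrix(Pat), label = "Pat")
  R <- check_psd_(as.matrix(R), label = "R")
  t <- nrow(G)
  stopifnot(nrow(Mat) == t, nrow(Pat) == t, nrow(R) == t)
  if (is.null(beta)) beta <- numeric(t)
  swap <- scheme_swap_(scheme)
  refl <- template; refl[, 1L] <- -refl[, 1L]
  if (max(abs(template - refl[swap, ])) > 1e-12)
    stop("template is not exactly bilaterally symmetric under the scheme",
         call. = FALSE)
  basis <- symmetric_basis_(template, scheme)
  if (t > ncol(basis))
    stop(sprintf("t = %d exceeds the symmetric-space dimension %d",
                 t, ncol(basis)), call. = FALSE)
  structure(list(template = template, scheme = scheme, basis = basis,
                 G = G, Mat = Mat, Pat = Pat, R = R, beta = as.numeric(beta),
                 cs_mean = cs_mean, cs_sd = cs_sd,
                 asym_noise_sd = asym_noise_sd, seed = as.integer(seed)),
            class = "simulation_truth")
}

#' Simulate a landmark dataset under the animal model
#'
#' For each phenotyped individual, draws log centroid size, composes the
#' trait-space shape deviation `beta (logCS - mean) + a + m_dam + p_sire
#' + e` (breeding values follow the pedigree; maternal and paternal
#' effects are i.i.d. per dam / sire; residuals i.i.d. per individual),
#' maps it to landmarks through a fixed orthonormal basis of the symmetric
#' tangent space at the template, adds i.i.d. asymmetric digitization
#' noise per coordinate, and applies a random rotation, translation, and
#' the scale `exp(logCS)`.
#'
#' @param truth A [simulation_truth()].
#' @param ped A [pedigree()].
#' @param phenotyped Ids to phenotype (default: every pedigree member).
#' @return List with `configs` (TPS-writable configurations), `truth_table`
#'   (data frame: id, dam, sire, sex, family, log_cs, true trait
#'   deviations `z.*` and their components `a.*`, `m.*`, `p.*`, `e.*`),
#'   and the `basis` used.
#' @export
simulate_dataset <- function(truth, ped, phenotyped = ped$id) {
  stopifnot(inherits(truth, "simulation_truth"))
  t <- nrow(truth$G)
  basis <- truth$basis[, seq_len(t), drop = FALSE]
  ids <- as.character(phenotyped)
  pos <- match(ids, ped$id)
  if (anyNA(pos)) stop("phenotyped ids missing from the pedigree",
                       call. = FALSE)
  n <- length(ids)

  seeds <- with_seed_(truth$seed, sample.int(2000000000L, 2L))
  a_all <- simulate_breeding_values(ped, truth$G, seed = seeds[1L])
  dams <- unique(stats::na.omit(ped$dam))
  sires <- unique(stats::na.omit(ped$sire))

  sim <- with_seed_(seeds[2L], {
    m_eff <- rmvn_(length(dams), truth$Mat)
    rownames(m_eff) <- dams
    p_eff <- rmvn_(length(sires), truth$Pat)
    rownames(p_eff) <- sires
    e_eff <- rmvn_(n, truth$R)
    log_cs <- stats::rnorm(n, truth$cs_mean, truth$cs_sd)
    rot <- stats::runif(n, 0, 2 * pi)
    trans <- matrix(stats::runif(2L * n, -50, 50), n, 2L)
    noise <- matrix(stats::rnorm(n * 2L * nrow(truth$template), 0,
                                 truth$asym_noise_sd),
                    n, 2L * nrow(truth$template))
    list(m_eff = m_eff, p_eff = p_eff, e_eff = e_eff, log_cs = log_cs,
         rot = rot, trans = trans, noise = noise)
  })

  a <- a_all[ids, , drop = FALSE]
  dam_i <- ped$dam[pos]; sire_i <- ped$sire[pos]
  m <- matrix(0, n, t)
  known_d <- !is.na(dam_i)
  m[known_d, ] <- sim$m_eff[dam_i[known_d], , drop = FALSE]
  p <- matrix(0, n, t)
  known_s <- !is.na(sire_i)
  p[known_s, ] <- sim$p_eff[sire_i[known_s], , drop = FALSE]
  z <- outer(sim$log_cs - truth$cs_mean, truth$beta) + a + m + p + sim$e_eff

  tmpl <- flatten_(truth$template)
  configs <- vector("list", n)
  role <- ifelse(ped$id[pos] %in% ped$dam, "dam",
                 ifelse(ped$id[pos] %in% ped$sire, "sire", "offspring"))
  for (i in seq_len(n)) {
    v <- tmpl + drop(basis %*% z[i, ]) + sim$noise[i, ]
    X <- unflatten_(v)
    th <- sim$rot[i]
    Rm <- cbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
    X <- exp(sim$log_cs[i]) * (X %*% Rm)
    X <- sweep(X, 2L, sim$trans[i, ], `+`)
    configs[[i]] <- list(id = ids[i], coords = X,
                         metadata = list(sex = ped$sex[pos][i],
                                         family = ped$family[pos][i],
                                         role = role[i]))
  }

  tab <- data.frame(id = ids, dam = dam_i, sire = sire_i,
                    sex = if (!is.null(ped$sex)) ped$sex[pos] else NA,
                    family = if (!is.null(ped$family)) ped$family[pos]
                             else NA,
                    log_cs = sim$log_cs, stringsAsFactors = FALSE)
  add_block <- function(tab, mat, prefix) {
    colnames(mat) <- paste0(prefix, ".", seq_len(ncol(mat)))
    cbind(tab, mat)
  }
  tab <- add_block(tab, z, "z")
  tab <- add_block(tab, a, "a")
  tab <- add_block(tab, m, "m")
  tab <- add_block(tab, p, "p")
  tab <- add_block(tab, sim$e_eff, "e")
  rownames(tab) <- NULL
  list(configs = configs, truth_table = tab, basis = basis,
       scheme = truth$scheme, template = truth$template)
}

#' Preset simulation designs
#'
#' `"viper"`: the captive-breeding design this package emulates --
#' 12 families from 8 dams x 6 sires with 221 offspring (family sizes
#' near-equal), three trait dimensions with trace
#' proportions G 49.13%, Mat 50.69%, Pat 8.85e-4% and the remainder
#' residual, with strongly concentrated G and Mat eigenstructure
#' and divergent leading eigenvectors.
#'
#' `"recovery"`: a larger design for parameter-recovery checks -- 80
#' families from 40 dams x 30 sires with 800 offspring and trace
#' proportions G:Mat:Pat:R = 0.45:0.45:0:0.10.
#'
#' @param name `"viper"` or `"recovery"`.
#' @param seed Integer seed used for both the pedigree and the dataset.
#' @return List with `ped` (a [pedigree()]) and `truth`
#'   (a [simulation_truth()]).
#' @export
simulation_preset <- function(name = c("viper", "recovery"), seed = 1L) {
  name <- match.arg(name)
  rot12 <- function(deg) {
    th <- deg * pi / 180
    cbind(c(cos(th), sin(th), 0), c(-sin(th), cos(th), 0), c(0, 0, 1))
  }
  Vg <- diag(3)
  Vm <- rot12(72.51)
  G0 <- Vg %*% diag(c(0.91, 0.06, 0.03)) %*% t(Vg)
  M0 <- Vm %*% diag(c(0.77, 0.15, 0.08)) %*% t(Vm)
  R0 <- diag(3) / 3
  total <- 4.5e-4   # total shape variance (squared Procrustes units)
  if (name == "viper") {
    props <- c(G = 0.4913, Mat = 0.5069, Pat = 8.85e-6)
    props <- c(props, R = 1 - sum(props))
    ped <- simulate_pedigree(8L, 6L, 12L,
                             c(rep(19L, 5L), rep(18L, 7L)), seed = seed)
  } else {
    props <- c(G = 0.45, Mat = 0.45, Pat = 0, R = 0.10)
    ped <- simulate_pedigree(40L, 30L, 80L, rep(10L, 80L), seed = seed)
  }
  truth <- simulation_truth(
    G = total * props["G"] * G0,
    Mat = total * props["Mat"] * M0,
    Pat = total * props["Pat"] * diag(3) / 3,
    R = total * props["R"] * R0,
    beta = c(0.02, 0.01, 0),
    cs_mean = log(25), cs_sd = 0.15, asym_noise_sd = 0.002,
    seed = seed)
  list(ped = ped, truth = truth)
}
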