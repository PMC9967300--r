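# Internal geometry / RNG helpers shared across modules.

# CODATA 2018 constants; K_CM_PER_D2_NM3 is the Coulomb energy of 1 D x 1 D at
# 1 nm in vacuum, expressed in cm^-1. All couplings are K * D^2/nm / n^2 terms.
.const <- local({
  debye <- 1e-21 / 299792458          # 1 D in C*m
  eps0 <- 8.8541878128e-12            # F/m
  h <- 6.62607015e-34                 # J*s
  c_cm <- 2.99792458e10               # cm/s
  e_charge <- 1.602176634e-19         # C
  joule <- debye^2 / (4 * pi * eps0 * 1e-27)  # J, for 1 D^2 / 1 nm^3
  list(
    K_cm = joule / (h * c_cm),        # ~5.0341 cm^-1
    K_meV = joule / e_charge * 1e3    # ~0.6242 meV
  )
})

vec_norm <- function(v) sqrt(sum(v^2))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalize a near-zero vector", call. = FALSE)
  v / n
}

# Rotation matrix for a rotation of `angle_deg` degrees about `axis`
# (Rodrigues formula).
rotation_matrix <- function(axis, angle_deg) {
  k <- unit_vec(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

random_unit_vector <- function() unit_vec(rnorm(3))

# Run `code` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. Keeps analysis code free of RNG side effects.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
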