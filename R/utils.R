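# Shared helpers: variable-role bookkeeping, calibration tables, small stats.

DIET_VARS <- c("iron", "zinc", "calcium", "vit_a", "vit_b6", "folate",
               "vit_b12", "vit_c", "protein")
MEDIATOR_VARS <- c("mpo", "neo", "aat", "lmz")
INFLAMMATION_VAR <- "agp"
OUTCOME_VARS <- c("low_ferritin", "high_tfr", "low_retinol", "low_zinc")
ANEMIA_VAR <- "anemia"

# Deficiency thresholds; all comparisons are strict, in the stated direction.
DEFICIENCY_THRESHOLDS <- list(
  anemia       = list(analyte = "hemoglobin", cut = 11.0, dir = "<"),
  low_retinol  = list(analyte = "retinol",    cut = 0.70, dir = "<"),
  low_zinc     = list(analyte = "zinc",       cut = 9.9,  dir = "<"),
  low_ferritin = list(analyte = "ferritin",   cut = 12,   dir = "<"),
  high_tfr     = list(analyte = "tfr",        cut = 8.3,  dir = ">"),
  elevated_agp = list(analyte = "agp",        cut = 1.0,  dir = ">")
)

# Layer index used to enforce the a-priori DAG ordering:
# diet (1) -> EED biomarkers / systemic inflammation (2) ->
# deficiency outcomes (3) -> anemia (4).
node_layer <- function(node) {
  layer <- ifelse(node %in% DIET_VARS, 1L,
           ifelse(node %in% c(MEDIATOR_VARS, INFLAMMATION_VAR), 2L,
           ifelse(node %in% OUTCOME_VARS, 3L,
           ifelse(node == ANEMIA_VAR, 4L, NA_integer_))))
  if (anyNA(layer)) {
    stop("unknown node(s): ", paste(node[is.na(layer)], collapse = ", "))
  }
  layer
}

node_family <- function(node) {
  ifelse(node_layer(node) >= 3L, "logistic", "linear")
}

# calibration-scale variable name for each latent/observable
calib_variable <- function(node) {
  map <- c(mpo = "ln_mpo", neo = "ln_neo", aat = "ln_aat",
           lmz = "lmz", manz = "manz", agp = "ln_agp")
  ifelse(node %in% DIET_VARS, paste0("sqrt_", node),
         unname(map[node]))
}

eed_extdata <- function(file) {
  path <- system.file("extdata", file, package = "eednet")
  if (!nzchar(path)) stop("bundled data file not found: ", file)
  path
}

weighted_mean <- function(x, w) sum(x * w) / sum(w)

# Pooled location/scale and per-site standardized deviations for one
# observable, from site means/SDs and site sizes.
pool_sites <- function(means, sds, n) {
  w <- n / sum(n)
  center <- sum(w * means)
  v_between <- sum(w * (means - center)^2)
  v_within <- sum(w * sds^2)
  scale <- sqrt(v_between + v_within)
  list(center = center, scale = scale,
       dev = (means - center) / scale,
       within_sd = sds / scale)
}

logit <- function(p) qlogis(p)
inv_logit <- function(x) plogis(x)

# deterministic substream seed from a master seed and a counter.
# Linearly related seeds fed to the Mersenne-Twister initializer produce
# detectably correlated streams, so the pair is passed through a full
# avalanche hash (murmur3 finalizer) before seeding. Exact 32-bit modular
# multiplication is done on 16-bit halves to stay within double precision.
substream_seed <- function(seed, counter) {
  mul32 <- function(a, b) {
    a_lo <- a %% 65536
    a_hi <- (a - a_lo) / 65536
    (((a_hi * b) %% 65536) * 65536 + a_lo * b) %% 4294967296
  }
  x <- (as.numeric(seed) %% 4294967296)
  x <- bitwXor32(x, mul32(as.numeric(counter) %% 4294967296, 2654435769))
  x <- bitwXor32(x, floor(x / 65536))          # x ^= x >> 16
  x <- mul32(x, 2246822507)                    # 0x85EBCA6B
  x <- bitwXor32(x, floor(x / 8192))           # x ^= x >> 13
  x <- mul32(x, 3266489909)                    # 0xC2B2AE35
  x <- bitwXor32(x, floor(x / 65536))
  as.integer(x %% 2147483647)
}

# xor of two nonnegative doubles holding 32-bit values
bitwXor32 <- function(a, b) {
  a_lo <- a %% 65536
  a_hi <- (a - a_lo) / 65536
  b_lo <- b %% 65536
  b_hi <- (b - b_lo) / 65536
  xor16 <- function(u, v) {
    r <- 0
    p <- 1
    for (k in 1:16) {
      r <- r + p * ((u + v) %% 2)
      u <- u %/% 2
      v <- v %/% 2
      p <- p * 2
    }
    r
  }
  xor16(a_hi, b_hi) * 65536 + xor16(a_lo, b_lo)
}
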