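# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# md5 of an R object's serialization (version fixed for stability).
objectMd5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  con <- file(f, "wb")
  serialize(x, con, version = 3L)
  close(con)
  unname(tools::md5sum(f))
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

# round-half-up to integer (base round() rounds half to even)
roundHalfUp <- function(x) floor(x + 0.5)

# Block-mean downsample a numeric matrix to g x g (blocks as equal as possible).
blockMean <- function(m, g) {
  rg <- rep(seq_len(g), each = ceiling(nrow(m) / g), length.out = nrow(m))
  cg <- rep(seq_len(g), each = ceiling(ncol(m) / g), length.out = ncol(m))
  s <- rowsum(t(rowsum(m, rg)), cg)          # g x g sums (transposed)
  n <- tabulate(rg, g) %o% tabulate(cg, g)
  t(s) / n
}

assertFrameArray <- function(img, what = "image") {
  if (!is.array(img) || length(dim(img)) != 3 || dim(img)[3] != 3)
    stop(sprintf("'%s' must be an HxWx3 array", what), call. = FALSE)
  invisible(img)
}

# canonical class order everywhere: no_pain first, pain second
painClasses <- function() c("no_pain", "pain")

normalizeLabel <- function(x) {
  y <- gsub("[ -]+", "_", tolower(trimws(x)))
  y[y == "nopain"] <- "no_pain"
  y
}
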