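# programmatic fixtures shared across test files

unitCube <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  f <- rbind(c(1, 3, 2), c(1, 4, 3),   # z = 0
             c(5, 6, 7), c(5, 7, 8),   # z = 1
             c(1, 2, 6), c(1, 6, 5),   # y = 0
             c(3, 4, 8), c(3, 8, 7),   # y = 1
             c(1, 5, 8), c(1, 8, 4),   # x = 0
             c(2, 3, 7), c(2, 7, 6))   # x = 1
  TriMesh(v, f, name = "cube")
}

singleTriangle <- function() {
  TriMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(c(1L, 2L, 3L)),
          name = "tri")
}

randomRotationMatrix <- function() {
  m <- matrix(stats::rnorm(9), 3L)
  R <- qr.Q(qr(m))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# small toy cyst reused by morphometry tests (built once per session)
.smallCystEnv <- new.env()
smallToyCyst <- function() {
  if (is.null(.smallCystEnv$scene))
    .smallCystEnv$scene <- makeToyCyst(ToyCystConfig(nLDs = 40L,
                                                     LDFraction = 0.03,
                                                     nMitochondria = 12L,
                                                     seed = 5L))
  .smallCystEnv$scene
}

defaultToyCyst <- function() {
  if (is.null(.smallCystEnv$default))
    .smallCystEnv$default <- makeToyCyst()
  .smallCystEnv$default
}
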