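# Exact reduced-fraction arithmetic on IEEE doubles.
#
# Numerators and denominators are kept as integers stored in doubles, reduced
# by their gcd after every operation, with a hard guard at 2^53 (the largest
# magnitude at which every integer is exactly representable). Within that
# range every operation below is exact, which is all the Price-identity
# checks require at their problem sizes.

.RAT_MAX <- 2^53

.gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { r <- a %% b; a <- b; b <- r }
  a
}

.rat_check <- function(x) {
  if (any(abs(x$num) >= .RAT_MAX) || any(abs(x$den) >= .RAT_MAX))
    stop("rational overflow: magnitude exceeds 2^53; exact mode is only ",
         "supported at small problem sizes", call. = FALSE)
  x
}

# construct (vectorised); num, den integers in doubles
rat <- function(num, den = 1) {
  stopifnot(length(den) %in% c(1L, length(num)), all(den != 0))
  den <- rep_len(den, length(num))
  s <- ifelse(den < 0, -1, 1)
  num <- num * s; den <- den * s
  g <- mapply(.gcd2, num, den)
  g[g == 0] <- 1
  .rat_check(structure(list(num = num / g, den = den / g), class = "rat"))
}

rat_add <- function(x, y) {
  g <- mapply(.gcd2, x$den, y$den)
  dx <- x$den / g; dy <- y$den / g
  rat(x$num * dy + y$num * dx, x$den * dy)
}

rat_sub <- function(x, y) rat_add(x, rat(-y$num, y$den))

rat_mul <- function(x, y) {
  # cross-reduce before multiplying to delay overflow
  g1 <- mapply(.gcd2, x$num, y$den); g1[g1 == 0] <- 1
  g2 <- mapply(.gcd2, y$num, x$den); g2[g2 == 0] <- 1
  rat((x$num / g1) * (y$num / g2), (x$den / g2) * (y$den / g1))
}

rat_div <- function(x, y) {
  stopifnot(all(y$num != 0))
  rat_mul(x, rat(y$den, y$num))
}

rat_sum <- function(x) {
  acc <- rat(0)
  for (i in seq_along(x$num)) acc <- rat_add(acc, rat(x$num[i], x$den[i]))
  acc
}

rat_scale <- function(x, k) rat_mul(x, rat(rep_len(k, length(x$num))))

rat_num <- function(x) x$num / x$den
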