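# random group-record generators used by the property tests

# groups with equal initial sizes (the worked-example regime: equal-weight
# and pooled community frequencies coincide)
random_groups_equal_size <- function(n_groups, size = 6) {
  k <- sample(0:size, n_groups, replace = TRUE)
  pi_ <- sample(0:40, n_groups, replace = TRUE)
  kf <- vapply(pi_, function(p) sample(0:p, 1), integer(1))
  group_records(rep(size, n_groups), k, pi_, kf)
}

# fully random sizes 1..20 (unequal initial sizes)
random_groups <- function(n_groups, max_size = 20) {
  n <- sample(seq_len(max_size), n_groups, replace = TRUE)
  k <- vapply(n, function(s) sample(0:s, 1), integer(1))
  pi_ <- sample(0:(2 * max_size), n_groups, replace = TRUE)
  kf <- vapply(pi_, function(p) sample(0:p, 1), integer(1))
  group_records(n, k, pi_, kf)
}

# a cell made of pure mitochondria: n_f all-functional + n_d all-dysfunctional
pure_mito_cell <- function(n_f, n_d, copies = 10) {
  cell_state(rbind(
    if (n_f > 0) cbind(rep(copies, n_f), rep(0, n_f)),
    if (n_d > 0) cbind(rep(0, n_d), rep(copies, n_d))))
}
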