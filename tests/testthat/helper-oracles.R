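# independent oracles used across tests -- deliberately written without the
# package's numerics (plain softmax arithmetic, no log-sum-exp tricks)

oracle_softmax <- function(z) exp(z) / sum(exp(z))

oracle_perplexity <- function(z) -log(oracle_softmax(z)[length(z)])

oracle_cross_entropy <- function(prob_rows, labels) {
  -mean(log(prob_rows[cbind(seq_along(labels), labels)]))
}

# small random feature_dataset for container tests
random_dataset <- function(n = 10, ch = 4, bands = 2, seed = 1,
                           subjects = c("S01", "S02")) {
  withr::with_seed(seed, {
    feature_dataset(array(rnorm(n * ch * bands), c(n, ch, bands)),
                    labels = rep_len(1:3, n),
                    subject_id = rep_len(subjects, n),
                    session_id = rep_len(c("ses1", "ses2"), n),
                    channel_names = sprintf("CH%d", seq_len(ch)),
                    band_names = utils::head(c("alpha", "beta", "gamma"), bands))
  })
}

# small source/target matrices for training tests: two Gaussian classes with
# a mean shift on the target
tiny_task <- function(seed = 1, d = 6, n = 60) {
  withr::with_seed(seed, {
    y <- rep_len(1:2, n)
    mu <- rbind(c(rep(2, d / 2), rep(0, d / 2)),
                c(rep(0, d / 2), rep(2, d / 2)))
    xs <- mu[y, ] + matrix(rnorm(n * d), n, d)
    xt <- mu[y, ] + 1.5 + matrix(rnorm(n * d), n, d)
    list(xs = xs, ys = y, xt = xt, yt = y)
  })
}
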