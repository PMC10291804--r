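# Fixtures built in code: small banks and simulated datasets shared across
# test files. Everything is seeded and deterministic.

# one dichotomous item on the general factor only (a = 1, d = 0)
bank_1pl <- function() {
  item_bank(data.frame(item_id = "i1", group_index = 0L, n_categories = 2L,
                       a_general = 1, a_group = 0, d1 = 0))
}

# the 4-category worked item: a_gen = 2, a_grp = 1 (group 1), d = (2, 0, -2)
bank_k4 <- function(G = 2L) {
  item_bank(data.frame(item_id = "k4", group_index = 1L, n_categories = 4L,
                       a_general = 2, a_group = 1,
                       d1 = 2, d2 = 0, d3 = -2), G = G)
}

# small mixed bank: 2 group factors + one general-only item, mixed K
bank_small <- function() {
  df <- data.frame(
    item_id = sprintf("s%d", 1:5),
    group_index = c(1L, 1L, 2L, 2L, 0L),
    n_categories = c(2L, 4L, 3L, 5L, 3L),
    a_general = c(1.2, 2.0, 1.5, 2.4, 1.0),
    a_group = c(0.8, 1.1, 1.6, 0.9, 0),
    d1 = c(0.3, 2.0, 1.1, 2.2, 0.8),
    d2 = c(NA, 0.1, -0.7, 0.9, -0.9),
    d3 = c(NA, -1.8, NA, -0.4, NA),
    d4 = c(NA, NA, NA, -1.9, NA))
  item_bank(df, G = 2L)
}

# 20-item, 2-group calibration bank used by the recovery tests
bank_recovery <- function(seed = 11) {
  generate_item_bank(
    bank_spec(G = 2L, items_per_factor = c(g1 = 10L, g2 = 10L),
              n_general_only = 0L, categories_per_factor = c(4L, 4L),
              a_general_range = c(0.9, 2.5), a_group_range = c(0.9, 2.5)),
    seed = seed)
}
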