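# shared scan helpers for the transition-phenomenology tests

scan_protocol <- function(g, dt = 1e-4)
  sim_config(dt = dt, g = g, t_transient = 12, t_observe = 6)

reference_protocol <- function(g)
  sim_config(g = g, t_transient = 48, t_observe = 12)

# mean S (and R) over seeds for one topology/drive/coupling combination
mean_sync <- function(make_adj, drive, cfg, seeds) {
  v <- vapply(seeds, function(s) {
    set.seed(s)
    adj <- make_adj()
    tr <- suppressWarnings(run_network(adj, cfg, drive = drive))
    sm <- sync_from_spikes(tr)
    c(S = sm$S, R = sm$R)
  }, numeric(2))
  rowMeans(v)
}

scan_S <- function(make_adj, drive, grid, seeds, dt = 1e-4) {
  vapply(grid, function(g)
    mean_sync(make_adj, drive, scan_protocol(g, dt), seeds)[["S"]],
    numeric(1))
}
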