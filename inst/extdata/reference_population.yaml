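# Labelled reference particle population for offline classifier validation.
#
# Synthetic distribution parameters, chosen to mirror the qualitative
# behaviour of optimally Nile-red-stained reference particles: the six
# polymer classes are bright (total particle brightness on the order of
# the 88 +/- 18 regime reported for optimal staining, down to the
# medium-bright 70s) with plastic-typical red fractions around 0.5, so
# that roughly 1% of each polymer class falls below the MP thresholds.
# The four natural-particle classes are weakly fluorescent and/or
# off-colour; chitin sits closest to the MP region and contributes about
# 1% false positives. These are fixture assumptions, not measured values.
#
# tpb: normal(mean, sd) truncated to [0, 255]
# red_fraction: normal(mean, sd) truncated to [0.02, 0.98]
# size_um: log-normal(median, log_sd) truncated to [5, 5000]
# shape_probs: mixture over fragment / spheroid / fibre
classes:
  - label: PA6
    truth: MP
    count: 100
    tpb_mean: 92
    tpb_sd: 15
    red_mean: 0.52
    red_sd: 0.05
    size_median_um: 25
    size_log_sd: 0.35
    shape_probs: {fragment: 0.8, spheroid: 0.2, fibre: 0.0}
  - label: PE
    truth: MP
    count: 100
    tpb_mean: 78
    tpb_sd: 14
    red_mean: 0.50
    red_sd: 0.05
    size_median_um: 60
    size_log_sd: 0.6
    shape_probs: {fragment: 0.9, spheroid: 0.1, fibre: 0.0}
  - label: PET
    truth: MP
    count: 100
    tpb_mean: 74
    tpb_sd: 12
    red_mean: 0.55
    red_sd: 0.05
    size_median_um: 40
    size_log_sd: 0.5
    shape_probs: {fragment: 1.0, spheroid: 0.0, fibre: 0.0}
  - label: PP
    truth: MP
    count: 100
    tpb_mean: 76
    tpb_sd: 13
    red_mean: 0.48
    red_sd: 0.05
    size_median_um: 70
    size_log_sd: 0.6
    shape_probs: {fragment: 0.9, spheroid: 0.1, fibre: 0.0}
  - label: PS
    truth: MP
    count: 100
    tpb_mean: 88
    tpb_sd: 18
    red_mean: 0.52
    red_sd: 0.05
    size_median_um: 30
    size_log_sd: 0.4
    shape_probs: {fragment: 0.5, spheroid: 0.5, fibre: 0.0}
  - label: PVC
    truth: MP
    count: 100
    tpb_mean: 82
    tpb_sd: 15
    red_mean: 0.56
    red_sd: 0.05
    size_median_um: 80
    size_log_sd: 0.5
    shape_probs: {fragment: 1.0, spheroid: 0.0, fibre: 0.0}
  - label: fishbone
    truth: PNO
    count: 100
    tpb_mean: 20
    tpb_sd: 10
    red_mean: 0.30
    red_sd: 0.04
    size_median_um: 50
    size_log_sd: 0.5
    shape_probs: {fragment: 1.0, spheroid: 0.0, fibre: 0.0}
  - label: chitin
    truth: PNO
    count: 100
    tpb_mean: 30
    tpb_sd: 7
    red_mean: 0.40
    red_sd: 0.05
    size_median_um: 80
    size_log_sd: 0.5
    shape_probs: {fragment: 0.8, spheroid: 0.0, fibre: 0.2}
  - label: mussel_shell
    truth: PNO
    count: 100
    tpb_mean: 15
    tpb_sd: 8
    red_mean: 0.32
    red_sd: 0.06
    size_median_um: 60
    size_log_sd: 0.5
    shape_probs: {fragment: 1.0, spheroid: 0.0, fibre: 0.0}
  - label: cotton
    truth: PNO
    count: 100
    tpb_mean: 28
    tpb_sd: 12
    red_mean: 0.25
    red_sd: 0.05
    size_median_um: 300
    size_log_sd: 0.4
    shape_probs: {fragment: 0.0, spheroid: 0.0, fibre: 1.0}
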