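# Margin specification: carpal tunnel syndrome reports in FAERS,
# October 2003 - September 2024. Database totals, the ten drugs most
# strongly associated with the event (a = primary-suspect reports naming
# the event, n_drug = all primary-suspect reports), and the demographics
# of the event reports.
event_pt = carpal tunnel syndrome
n_total = 12929504
n_event = 6837
filler_drug = other suspect drug
filler_pt = drug ineffective
drug = idursulfase; 54; 2064
drug = galsulfase; 20; 1435
drug = laronidase; 28; 2577
drug = tesamorelin; 23; 2130
drug = anastrozole; 109; 10273
drug = alendronic acid; 151; 17251
drug = gamma-hydroxybutyric acid; 14; 1640
drug = rofecoxib; 268; 32890
drug = alendronate; 157; 23592
drug = tafamidis; 55; 8770
n_female = 4753
n_male = 1717
n_unknown = 367
age_mean = 57.0
age_sd = 14.9
country = united states; 4699
year_start = 2004
year_end = 2024
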