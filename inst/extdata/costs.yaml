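# Authoritative-mode cost configuration: unit-cost components, utilisation
# and break-even inputs carried from the hospital accounting tables.
# Currency in euros; decimal commas are accepted and normalised.
unit_costs:
  cxr:
    contrast: 0
    medical: 11.65
    radiographer: 3.05
    nursing: 0
    depreciation: 0.45
  dts:
    contrast: 0
    medical: 23.04
    radiographer: 7.92
    nursing: 0
    depreciation: 10.59
  ct_unenhanced:
    contrast: 0
    medical: 31.95
    radiographer: 7.07
    nursing: 6.98
    depreciation: 19.35
  ct_contrast:
    contrast: 25.83
    medical: 46.24
    radiographer: 11.19
    nursing: 11.05
    depreciation: 19.35
utilisation:
  before:
    cxr: 0
    dts: 0
    dts_subdiagnostic: 0
    ct: 271
  after:
    cxr: 91
    dts: 130
    dts_subdiagnostic: 7
    ct: 39
assets:
  dts:
    price: 30000
    useful_life_years: 10
    annual_maintenance: 10000
    capacity_hours_per_year: 2600
    printed_annual_depreciation: 3750
  ct:
    price: 1242000
    useful_life_years: 10
    annual_maintenance: 105996
    capacity_hours_per_year: 3030
    printed_annual_depreciation: 155250
capacity_hours:
  cxr: 2600
  dts: 2600
  ct: 3030
occupation_min:
  cxr: 6
  dts: 13
  ct_unenhanced: 15
  ct_contrast: 19
breakeven:
  fixed_cost: 30000
  reimbursement: 62.7
  variable_unit_cost: 0
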