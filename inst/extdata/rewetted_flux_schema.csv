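column,type,description
site_name,text,Site or study name as given in the compilation
category,enum,"One of: rewetted_general, rewetted_forest, paludiculture, shallow_lake, open_bog_fen"
subgroup,text,"Finer grouping where the compilation gives one (reed_grasses, vaccinium, sphagnum, global review, ...)"
country,text,Country of the study site (blank for multi-country reviews)
latitude,decimal degrees,"Site latitude, converted from printed degrees-minutes-seconds at encoding time; blank when not printed"
longitude,decimal degrees,"Site longitude; negative = west"
period,text,Measurement period as printed
nutrient_status,enum,"One of: rich, poor, mixed, unknown; blank when not stated"
treatment,text,Plant community and/or treatment description
record_type,enum,"site = one measured site/treatment; review = a row aggregating several literature sites"
nee,text,"Net ecosystem CO2 exchange cell exactly as tabulated: a number, 'a to b' range, or 'x ± s'; negative = uptake"
ch4,text,CH4 flux cell as tabulated
n2o,text,N2O flux cell as tabulated
nee_unit,text,Measurement unit of the NEE value per the compilation footnote for this study
ch4_unit,text,Measurement unit of the CH4 value
n2o_unit,text,Measurement unit of the N2O value
spread_kind,enum,"sd or se: how the study reports its ± spread; blank when no spread"
flags,text,"Semicolon-separated tokens: season_only (growing-season rate, no season-to-year rule), co2_equivalent (value is a CO2-equivalent mass), ambiguous_unit (footnote unit irreconcilable with the running text or tabulated magnitude), ambiguous_cell (typography of the printed cell admits several readings), lab_mesocosm"
note,text,Free-text provenance note explaining any flag
source,citation key,Study identifier
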