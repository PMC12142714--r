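alias	country
united states	United States
united states of america	United States
usa	United States
us	United States
u.s.a.	United States
united kingdom	United Kingdom
uk	United Kingdom
great britain	United Kingdom
england	United Kingdom
scotland	United Kingdom
wales	United Kingdom
northern ireland	United Kingdom
new zealand	New Zealand
aotearoa	New Zealand
china	China
people's republic of china	China
japan	Japan
taiwan	Taiwan
uruguay	Uruguay
france	France
switzerland	Switzerland
germany	Germany
australia	Australia
canada	Canada
italy	Italy
spain	Spain
portugal	Portugal
netherlands	Netherlands
the netherlands	Netherlands
belgium	Belgium
denmark	Denmark
sweden	Sweden
norway	Norway
finland	Finland
ireland	Ireland
austria	Austria
greece	Greece
brazil	Brazil
argentina	Argentina
chile	Chile
mexico	Mexico
india	India
south korea	South Korea
republic of korea	South Korea
korea	South Korea
russia	Russia
russian federation	Russia
south africa	South Africa
kenya	Kenya
nigeria	Nigeria
egypt	Egypt
israel	Israel
turkey	Turkey
thailand	Thailand
vietnam	Vietnam
viet nam	Vietnam
indonesia	Indonesia
malaysia	Malaysia
philippines	Philippines
singapore	Singapore
fiji	Fiji
papua new guinea	Papua New Guinea
colombia	Colombia
peru	Peru
ecuador	Ecuador
czech republic	Czech Republic
czechia	Czech Republic
poland	Poland
hungary	Hungary
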