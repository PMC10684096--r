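"name","alpha2","alpha3"
"Aruba","AW","ABW"
"Afghanistan","AF","AFG"
"Angola","AO","AGO"
"Anguilla","AI","AIA"
"Aland Islands","AX","ALA"
"Albania","AL","ALB"
"Andorra","AD","AND"
"United Arab Emirates","AE","ARE"
"Argentina","AR","ARG"
"Armenia","AM","ARM"
"American Samoa","AS","ASM"
"Antarctica","AQ","ATA"
"French Southern and Antarctic Lands","TF","ATF"
"Antigua and Barbuda","AG","ATG"
"Australia","AU","AUS"
"Austria","AT","AUT"
"Azerbaijan","AZ","AZE"
"Burundi","BI","BDI"
"Belgium","BE","BEL"
"Benin","BJ","BEN"
"Bonaire, Sint Eustatius and Saba","BQ","BES"
"Burkina Faso","BF","BFA"
"Bangladesh","BD","BGD"
"Bulgaria","BG","BGR"
"Bahrain","BH","BHR"
"Bahamas","BS","BHS"
"Bosnia and Herzegovina","BA","BIH"
"Saint Barthelemy","BL","BLM"
"Belarus","BY","BLR"
"Belize","BZ","BLZ"
"Bermuda","BM","BMU"
"Bolivia, Plurinational State of","BO","BOL"
"Brazil","BR","BRA"
"Barbados","BB","BRB"
"Brunei Darussalam","BN","BRN"
"Bhutan","BT","BTN"
"Bouvet Island","BV","BVT"
"Botswana","BW","BWA"
"Central African Republic","CF","CAF"
"Canada","CA","CAN"
"Cocos (Keeling) Islands","CC","CCK"
"Switzerland","CH","CHE"
"Chile","CL","CHL"
"China","CN","CHN"
"Cote d'Ivoire","CI","CIV"
"Cameroon","CM","CMR"
"Democratic Republic of the Congo","CD","COD"
"Republic of Congo","CG","COG"
"Cook Islands","CK","COK"
"Colombia","CO","COL"
"Comoros","KM","COM"
"Cape Verde","CV","CPV"
"Costa Rica","CR","CRI"
"Cuba","CU","CUB"
"Curacao","CW","CUW"
"Christmas Island","CX","CXR"
"Cayman Islands","KY","CYM"
"Cyprus","CY","CYP"
"Czech Republic","CZ","CZE"
"Germany","DE","DEU"
"Djibouti","DJ","DJI"
"Dominica","DM","DMA"
"Denmark","DK","DNK"
"Dominican Republic","DO","DOM"
"Algeria","DZ","DZA"
"Ecuador","EC","ECU"
"Egypt","EG","EGY"
"Eritrea","ER","ERI"
"Western Sahara","EH","ESH"
"Spain","ES","ESP"
"Estonia","EE","EST"
"Ethiopia","ET","ETH"
"Finland","FI","FIN"
"Fiji","FJ","FJI"
"Falkland Islands (Malvinas)","FK","FLK"
"France","FR","FRA"
"Faroe Islands","FO","FRO"
"Federated States of Micronesia","FM","FSM"
"Gabon","GA","GAB"
"United Kingdom of Great Britain and Northern Ireland","GB","GBR"
"Georgia","GE","GEO"
"Guernsey","GG","GGY"
"Ghana","GH","GHA"
"Gibraltar","GI","GIB"
"Guinea","GN","GIN"
"Guadeloupe","GP","GLP"
"Gambia","GM","GMB"
"Guinea-Bissau","GW","GNB"
"Equatorial Guinea","GQ","GNQ"
"Greece","GR","GRC"
"Grenada","GD","GRD"
"Greenland","GL","GRL"
"Guatemala","GT","GTM"
"French Guiana","GF","GUF"
"Guam","GU","GUM"
"Guyana","GY","GUY"
"Hong Kong","HK","HKG"
"Heard Island and McDonald Islands","HM","HMD"
"Honduras","HN","HND"
"Croatia","HR","HRV"
"Haiti","HT","HTI"
"Hungary","HU","HUN"
"Indonesia","ID","IDN"
"Isle of Man","IM","IMN"
"India","IN","IND"
"British Indian Ocean Territory","IO","IOT"
"Ireland","IE","IRL"
"Iran, Islamic Republic of","IR","IRN"
"Iraq","IQ","IRQ"
"Iceland","IS","ISL"
"Israel","IL","ISR"
"Italy","IT","ITA"
"Jamaica","JM","JAM"
"Jersey","JE","JEY"
"Jordan","JO","JOR"
"Japan","JP","JPN"
"Kazakhstan","KZ","KAZ"
"Kenya","KE","KEN"
"Kyrgyzstan","KG","KGZ"
"Cambodia","KH","KHM"
"Kiribati","KI","KIR"
"Saint Kitts and Nevis","KN","KNA"
"Republic of Korea","KR","KOR"
"Kuwait","KW","KWT"
"Lao People's Democratic Republic","LA","LAO"
"Lebanon","LB","LBN"
"Liberia","LR","LBR"
"Libya","LY","LBY"
"Saint Lucia","LC","LCA"
"Liechtenstein","LI","LIE"
"Sri Lanka","LK","LKA"
"Lesotho","LS","LSO"
"Lithuania","LT","LTU"
"Luxembourg","LU","LUX"
"Latvia","LV","LVA"
"Macao","MO","MAC"
"Saint Martin (French part)","MF","MAF"
"Morocco","MA","MAR"
"Monaco","MC","MCO"
"Moldova, Republic of","MD","MDA"
"Madagascar","MG","MDG"
"Maldives","MV","MDV"
"Mexico","MX","MEX"
"Marshall Islands","MH","MHL"
"Republic of North Macedonia","MK","MKD"
"Mali","ML","MLI"
"Malta","MT","MLT"
"Myanmar","MM","MMR"
"Montenegro","ME","MNE"
"Mongolia","MN","MNG"
"Northern Mariana Islands","MP","MNP"
"Mozambique","MZ","MOZ"
"Mauritania","MR","MRT"
"Montserrat","MS","MSR"
"Martinique","MQ","MTQ"
"Mauritius","MU","MUS"
"Malawi","MW","MWI"
"Malaysia","MY","MYS"
"Mayotte","YT","MYT"
"Namibia","NA","NAM"
"New Caledonia","NC","NCL"
"Niger","NE","NER"
"Norfolk Island","NF","NFK"
"Nigeria","NG","NGA"
"Nicaragua","NI","NIC"
"Niue","NU","NIU"
"Netherlands","NL","NLD"
"Norway","NO","NOR"
"Nepal","NP","NPL"
"Nauru","NR","NRU"
"New Zealand","NZ","NZL"
"Oman","OM","OMN"
"Pakistan","PK","PAK"
"Panama","PA","PAN"
"Pitcairn Islands","PN","PCN"
"Peru","PE","PER"
"Philippines","PH","PHL"
"Palau","PW","PLW"
"Papua New Guinea","PG","PNG"
"Poland","PL","POL"
"Puerto Rico","PR","PRI"
"Democratic People's Republic of Korea","KP","PRK"
"Portugal","PT","PRT"
"Paraguay","PY","PRY"
"Palestine, State of","PS","PSE"
"French Polynesia","PF","PYF"
"Qatar","QA","QAT"
"Reunion","RE","REU"
"Romania","RO","ROU"
"Russian Federation","RU","RUS"
"Rwanda","RW","RWA"
"Saudi Arabia","SA","SAU"
"Sudan","SD","SDN"
"Senegal","SN","SEN"
"Singapore","SG","SGP"
"South Georgia and the South Sandwich Islands","GS","SGS"
"Saint Helena, Ascension and Tristan da Cunha","SH","SHN"
"Svalbard and Jan Mayen","SJ","SJM"
"Solomon Islands","SB","SLB"
"Sierra Leone","SL","SLE"
"El Salvador","SV","SLV"
"San Marino","SM","SMR"
"Somalia","SO","SOM"
"Saint Pierre and Miquelon","PM","SPM"
"Serbia","RS","SRB"
"South Sudan","SS","SSD"
"Sao Tome and Principe","ST","STP"
"Suriname","SR","SUR"
"Slovakia","SK","SVK"
"Slovenia","SI","SVN"
"Sweden","SE","SWE"
"Swaziland","SZ","SWZ"
"Sint Maarten (Dutch part)","SX","SXM"
"Seychelles","SC","SYC"
"Syrian Arab Republic","SY","SYR"
"Turks and Caicos Islands","TC","TCA"
"Chad","TD","TCD"
"Togo","TG","TGO"
"Thailand","TH","THA"
"Tajikistan","TJ","TJK"
"Tokelau","TK","TKL"
"Turkmenistan","TM","TKM"
"Timor-Leste","TL","TLS"
"Tonga","TO","TON"
"Trinidad and Tobago","TT","TTO"
"Tunisia","TN","TUN"
"Turkey","TR","TUR"
"Tuvalu","TV","TUV"
"Taiwan","TW","TWN"
"Tanzania, United Republic of","TZ","TZA"
"Uganda","UG","UGA"
"Ukraine","UA","UKR"
"United States Minor Outlying Islands","UM","UMI"
"Uruguay","UY","URY"
"United States","US","USA"
"Uzbekistan","UZ","UZB"
"Holy See (Vatican City State)","VA","VAT"
"Saint Vincent and the Grenadines","VC","VCT"
"Venezuela, Bolivarian Republic of","VE","VEN"
"Virgin Islands, British","VG","VGB"
"Virgin Islands, U.S.","VI","VIR"
"Vietnam","VN","VNM"
"Vanuatu","VU","VUT"
"Wallis and Futuna","WF","WLF"
"Samoa","WS","WSM"
"Kosovo","XK","XKX"
"Yemen","YE","YEM"
"South Africa","ZA","ZAF"
"Zambia","ZM","ZMB"
"Zimbabwe","ZW","ZWE"
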