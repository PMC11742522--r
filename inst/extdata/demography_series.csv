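"year","births","net_migrants","target_population"
2000,4059000,1050000,282162400
2001,4026000,1050000,285092100
2002,4022000,1050000,287973100
2003,4090000,1050000,290874200
2004,4112000,1050000,293746400
2005,4138000,1050000,296592800
2006,4266000,1050000,299514900
2007,4316000,1050000,302434300
2008,4248000,1050000,305234000
2009,4131000,1050000,307866900
2010,3999000,1050000,310319300
2011,3954000,950000,312579200
2012,3953000,950000,314791100
2013,3932000,950000,316935100
2014,3988000,950000,319088500
2015,3978000,950000,321184300
2016,3946000,950000,323200300
2017,3856000,950000,325080300
2018,3792000,950000,326851800
2019,3748000,950000,328531300
2020,3614000,550000,329626100
2021,3664000,1e+06,331169200
2022,3667000,1e+06,332649200
2023,3591000,1e+06,333999000
2024,3570000,1e+06,335270200
2025,3560000,1e+06,336470100
2026,3556000,1e+06,337601700
2027,3551000,1e+06,338656800
2028,3547000,1e+06,339640800
2029,3542000,1e+06,340550200
2030,3538000,1e+06,341384000
2031,3534000,1e+06,342141000
2032,3529000,1e+06,342817500
2033,3525000,1e+06,343417200
2034,3520000,1e+06,343939400
2035,3516000,1e+06,344386000
2036,3512000,1e+06,344758600
2037,3507000,1e+06,345054900
2038,3503000,1e+06,345283600
2039,3498000,1e+06,345446400
2040,3494000,1e+06,345547600
2041,3490000,1e+06,345591300
2042,3485000,1e+06,345573700
2043,3481000,1e+06,345510000
2044,3476000,1e+06,345402700
2045,3472000,1e+06,345256800
2046,3468000,1e+06,345076600
2047,3463000,1e+06,344854900
2048,3459000,1e+06,344611100
2049,3454000,1e+06,344346800
2050,3450000,1e+06,344065700
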