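year,d13C_atm
1850,-6.4
1851,-6.403
1852,-6.406
1853,-6.409
1854,-6.412
1855,-6.415
1856,-6.418
1857,-6.421
1858,-6.424
1859,-6.427
1860,-6.43
1861,-6.433
1862,-6.436
1863,-6.439
1864,-6.442
1865,-6.445
1866,-6.448
1867,-6.451
1868,-6.454
1869,-6.457
1870,-6.46
1871,-6.463
1872,-6.466
1873,-6.469
1874,-6.472
1875,-6.475
1876,-6.478
1877,-6.481
1878,-6.484
1879,-6.487
1880,-6.49
1881,-6.493
1882,-6.496
1883,-6.499
1884,-6.502
1885,-6.505
1886,-6.508
1887,-6.511
1888,-6.514
1889,-6.517
1890,-6.52
1891,-6.523
1892,-6.526
1893,-6.529
1894,-6.532
1895,-6.535
1896,-6.538
1897,-6.541
1898,-6.544
1899,-6.547
1900,-6.55
1901,-6.555
1902,-6.56
1903,-6.565
1904,-6.57
1905,-6.575
1906,-6.58
1907,-6.585
1908,-6.59
1909,-6.595
1910,-6.6
1911,-6.605
1912,-6.61
1913,-6.615
1914,-6.62
1915,-6.625
1916,-6.63
1917,-6.635
1918,-6.64
1919,-6.645
1920,-6.65
1921,-6.655
1922,-6.66
1923,-6.665
1924,-6.67
1925,-6.675
1926,-6.68
1927,-6.685
1928,-6.69
1929,-6.695
1930,-6.7
1931,-6.7075
1932,-6.715
1933,-6.7225
1934,-6.73
1935,-6.7375
1936,-6.745
1937,-6.7525
1938,-6.76
1939,-6.7675
1940,-6.775
1941,-6.7825
1942,-6.79
1943,-6.7975
1944,-6.805
1945,-6.8125
1946,-6.82
1947,-6.8275
1948,-6.835
1949,-6.8425
1950,-6.85
1951,-6.86
1952,-6.87
1953,-6.88
1954,-6.89
1955,-6.9
1956,-6.91
1957,-6.92
1958,-6.93
1959,-6.94
1960,-6.95
1961,-6.985
1962,-7.02
1963,-7.055
1964,-7.09
1965,-7.125
1966,-7.16
1967,-7.195
1968,-7.23
1969,-7.265
1970,-7.3
1971,-7.329
1972,-7.358
1973,-7.387
1974,-7.416
1975,-7.445
1976,-7.474
1977,-7.503
1978,-7.532
1979,-7.561
1980,-7.59
1981,-7.609
1982,-7.628
1983,-7.647
1984,-7.666
1985,-7.685
1986,-7.704
1987,-7.723
1988,-7.742
1989,-7.761
1990,-7.78
1991,-7.804
1992,-7.828
1993,-7.852
1994,-7.876
1995,-7.9
1996,-7.924
1997,-7.948
1998,-7.972
1999,-7.996
2000,-8.02
2001,-8.046
2002,-8.072
2003,-8.098
2004,-8.124
2005,-8.15
2006,-8.176
2007,-8.202
2008,-8.228
2009,-8.254
2010,-8.28
2011,-8.31
2012,-8.34
2013,-8.37
2014,-8.4
2015,-8.43
2016,-8.458
2017,-8.486
2018,-8.514
2019,-8.542
2020,-8.57
2021,-8.595
2022,-8.62
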